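record_id	patient_id	transcript_count	cdr3_start	cdr3_end	germline_sequence	padded
MS-01_seq00001	MS-01	1936	11	27	SLRAEDTAVYYCARHWDGRNSFKLWTPWGQGTLVTVSS	FALSE
MS-01_seq00002	MS-01	1	11	23	SLSSEDTAVYYCARNARETYVMKWGRGTLVTVSS	FALSE
MS-01_seq00003	MS-01	40	11	32	SLRAEDTAVYYCARTQSTYPKPHMERPLHQRNWGQGTLVTVSS	FALSE
MS-02_seq00001	MS-02	3	11	27	QMNSLRAEDTACARYFELFMTNTTRRAWGKGTTVTVSS	FALSE
MS-02_seq00002	MS-02	653	11	22	TLYLQMNSLRACTTFPPEKVARWGQGTMVTVSS	FALSE
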