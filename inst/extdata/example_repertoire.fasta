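>MS-01_seq00001
SLRAEDTAVYYCARHWDGRNSFKLWTPWGQGTLVTVSS
>MS-01_seq00002
SLSSEDTAVYYCARNARETYVMKWGRGTLVTVSS
>MS-01_seq00003
SLRAEDTAVYYCARTQSTYPKPHMERPLHQRNWGQGTLVTVSS
>MS-02_seq00001
QMNSLRAEGTACARYFELFMTNTTRRAWGKGTTVTLSS
>MS-02_seq00002
TLYLQMNSLRACTTRPPEKVARWGQNTMVTVSS
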