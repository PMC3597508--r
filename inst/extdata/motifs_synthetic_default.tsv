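id	pattern	threshold	special_pos	special_aa	in_class
NTD	DKEYNQWTGH	0.8	NA	NA	TRUE
S1	MSNEWKDR	0.8	NA	NA	TRUE
S2	QDHYTNKE	0.8	NA	NA	TRUE
S3	WNDQTKYE	0.8	NA	NA	TRUE
H1	KPNEYWSD	0.8	NA	NA	TRUE
G1	GHNDSGKT	0.8	NA	NA	TRUE
G2	RGDTKWSE	0.8	NA	NA	TRUE
G3	DTPGHQDW	0.8	5	H	TRUE
G4	NKGDEQTY	0.8	NA	NA	TRUE
G5	SAGKWEDQ	0.8	NA	NA	TRUE
S1p	MSNEWKDS	0.8	NA	NA	FALSE
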