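sample_id	group	truth_fusion	called_fusion	rin_class	diagnosis
CBTS-1	A	P2RY8::CRLF2	P2RY8::CRLF2	>3	B-ALL
CBTS-18	A	P2RY8::CRLF2	P2RY8::CRLF2	>3	B-ALL
CBTS-6	A	P2RY8::CRLF2	P2RY8::CRLF2	>3	B-ALL
CBTS-4	A	SSBP2::CSF1R	SSBP2::CSF1R	>3	B-ALL
CBTS-22	A	NUP214::ABL1	NUP214::ABL1	>3	B-ALL
CBTS-23	A	P2RY8::CRLF2	P2RY8::CRLF2	>3	B-ALL
CBTS-24	A	P2RY8::CRLF2	P2RY8::CRLF2	>3	B-ALL
CBTS-2	A	P2RY8::CRLF2	P2RY8::CRLF2	>3	B-ALL
CBTS-3	A	P2RY8::CRLF2;MYO18B::ABL1	P2RY8::CRLF2;MYO18B::ABL1	>3	B-ALL
CBTS-8	A	P2RY8::CRLF2	P2RY8::CRLF2	>3	B-ALL
CBTS-17	A	P2RY8::CRLF2	P2RY8::CRLF2	>3	B-ALL
CBTS-7	A	NUP214::ABL1	NUP214::ABL1	>3	B-ALL
CBTS-16	A	PAX5::JAK2	PAX5::JAK2	>3	B-ALL
CBTS-25	A	ZBTB5::JAK2	ZBTB5::JAK2	>3	B-ALL
CBTS-15	A	ETV6::ABL1	-	>3	B-ALL
CBTS-9	A	-	-	>3	healthy
CBTS-10	A	-	-	>3	healthy
CBTS-11	A	-	-	>3	healthy
CBTS-12	A	-	-	>3	healthy
CBTS-13	A	-	-	>3	healthy
CBTS-14	A	-	-	>3	healthy
CBTS-5	A	-	-	>3	healthy
CBTS-19	A	-	-	>3	healthy
CBTS-20	A	-	-	>3	healthy
CBTS-21	A	-	-	>3	healthy
CBTS-26	A	-	-	>3	healthy
CBTS-30	B	P2RY8::CRLF2	P2RY8::CRLF2	<=3	B-ALL
CBTS-27	B	P2RY8::CRLF2	P2RY8::CRLF2	<=3	B-ALL
CBTS-29	B	EBF1::PDGFRB	EBF1::PDGFRB	<=3	B-ALL
CBTS-32	B	EBF1::PDGFRB	EBF1::PDGFRB	<=3	B-ALL
CBTS-35	B	PAX5::JAK2	PAX5::JAK2	<=3	B-ALL
CBTS-28	B	NUP214::ABL1	-	<=3	B-ALL
CBTS-34	B	P2RY8::CRLF2	-	<=3	B-ALL
CBTS-31	B	-	-	<=3	healthy
CBTS-33	B	-	-	<=3	healthy
CBTS-36	C	EBF1::PDGFRB	EBF1::PDGFRB	unknown	B-ALL
CBTS-38	C	IGH::EPOR	ENSG00000277856::EPOR	unknown	B-ALL
CBTS-37	C	unknown::CRLF2	-	unknown	B-ALL
CBTS-39	C	unknown::CRLF2	-	unknown	B-ALL
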