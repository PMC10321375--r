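name	pattern	side	spacer_length	cut_offset	description
SpCas9-NGG	NGG	three_prime	20	-3	Streptococcus pyogenes Cas9, canonical NGG PAM
SpCas9-NAG	NAG	three_prime	20	-3	SpCas9 alternative NAG PAM
SaCas9-NNGRRT	NNGRRT	three_prime	21	-3	Staphylococcus aureus Cas9
SaCas9-KKH	NNNRRT	three_prime	21	-3	SaCas9 KKH variant, relaxed PAM
NmeCas9	NNNNGATT	three_prime	24	-3	Neisseria meningitidis Cas9
CjCas9	NNNNRYAC	three_prime	22	-3	Campylobacter jejuni Cas9
StCas9	NNAGAAW	three_prime	20	-3	Streptococcus thermophilus Cas9
FnCas9	NGG	three_prime	20	-3	Francisella novicida Cas9
Cas12a-TTTV	TTTV	five_prime	23	18	AsCas12a (AsCpf1), T-rich 5' PAM
LbCas12a-TTTV	TTTV	five_prime	23	18	Lachnospiraceae bacterium Cas12a
FnCas12a-TTN	TTN	five_prime	23	18	Francisella novicida Cas12a
Cas12b-TTN	TTN	five_prime	20	14	Cas12b (C2c1), T-rich 5' PAM
xCas9-NG	NG	three_prime	20	-3	xCas9 evolved variant, NG PAM
SpCas9-NG	NG	three_prime	20	-3	SpCas9-NG engineered variant
SpG-NGN	NGN	three_prime	20	-3	SpG near-PAMless variant
SpRY-NRN	NRN	three_prime	20	-3	SpRY near-PAMless variant
ScCas9-NNG	NNG	three_prime	20	-3	Streptococcus canis Cas9
Cas12e-TTCN	TTCN	five_prime	20	14	Cas12e (CasX)
Cas12f-TTTR	TTTR	five_prime	20	14	Cas12f miniature nuclease
CasMINI-TTTR	TTTR	five_prime	20	14	CasMINI engineered Cas12f variant
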