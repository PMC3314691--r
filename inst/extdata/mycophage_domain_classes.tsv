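family	class	name
N1	N	L-Ala-D-Glu peptidase
N2	N	M23B-like hydrolase
N3	N	M23B-like hydrolase
N4	N	cysteine protease
N5	N	cysteine protease
M23	N	M23 peptidase
Ami-2A	CAT	N-acetylmuramoyl-L-alanine amidase
Ami-2B	CAT	N-acetylmuramoyl-L-alanine amidase
GH19	CAT	glycoside hydrolase family 19
GH25	CAT	glycoside hydrolase family 25
TG	CAT	lytic transglycosylase
C1	C	cell wall binding
C2	C	cell wall binding
C3	C	peptidoglycan binding domain
LGFP	C	LGFP repeat cell wall anchor
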