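quantity	value	unit	source
N_CUR1_mode	1327	diploid individuals	published ABC posterior mode, west group
N_CUR2_mode	588	diploid individuals	published ABC posterior mode, east group
N_ANC_mode	1975	diploid individuals	published ABC posterior mode, ancestral population
T_mode	783	generations	published ABC posterior mode, divergence time
Nm21_mode	1.738	migrants per generation	published ABC posterior mode, east-to-west migrants
gsm_shape_mode	1.594	unitless	published ABC posterior mode, per-locus rate gamma shape
p_gsm_mode	0.980	unitless	published ABC posterior mode, geometric step parameter
m_west_to_east	0.0077	per generation	published recent migration rate (assignment-based)
m_east_to_west	0.0085	per generation	published recent migration rate (assignment-based)
generation_length	25	years	published generation length
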