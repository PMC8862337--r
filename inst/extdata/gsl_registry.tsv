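name	gsl_class	mw	desulfo_mz	rt_min	k	is_internal_standard
Progoitrin	aliphatic	389	309	5.3	1.09	FALSE
Epiprogoitrin	aliphatic	389	309	5.8	1.09	FALSE
Sinigrin	aliphatic	359	279	6.8	1	TRUE
Gluconapin	aliphatic	373	293	10.2	1.11	FALSE
4-hydroxy-3-indolylmethyl GSL	indole	464	384	11.9	0.28	FALSE
Glucobrassicanapin	aliphatic	387	307	13.7	0.25	FALSE
Glucotropaeolin	aromatic	409	329	14.7	0.95	FALSE
Indolyl-3-methyl	indole	448	368	16.8	0.29	FALSE
4-methoxy-3-indolylmethyl GSL	indole	478	398	18.8	0.25	FALSE
(R,S)-Glucoisatisin	aliphatic	562	482	20.9;21.1	1	FALSE
1-methoxy-3-indolylmethyl GSL	indole	478	398	23.8	0.2	FALSE
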