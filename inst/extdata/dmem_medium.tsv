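exchange_id	max_uptake	is_output
EX_glc_D_e	1	1
EX_glu_L_e	1	1
EX_gly_e	2	0
EX_cys_L_e	1	0
EX_hdca_e	1	0
EX_o2_e	25	0
EX_nh4_c	5	1
EX_h2o_e	10	1
EX_ctrf_e	1	0
EX_lac_L_e	0	1
EX_gln_L_e	0	1
EX_ser_D_e	0	1
EX_gthrd_e	0	1
EX_co2_e	0	1
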