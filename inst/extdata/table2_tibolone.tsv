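ID	formula	description
T1	Tibolone[e] <=>	Tibolone exchange reaction
T2	Tibolone[e] <=> a3OHtibolone[e]	3a-hydroxytibolone interconversion
T3	Tibolone[e] <=> b3OHtibolone[e]	3b-hydroxytibolone interconversion
T4	Tibolone[e] -> d4tibolone[e]	D4-tibolone isomer formation
T5	b3OHtibolone[e] -> d4tibolone[e]	D4-tibolone isomer formation from 3b-hydroxytibolone
T6	a3OHtibolone[e] -> estradiol[c]	Estradiol receptor agonist action mechanism of 3a-hydroxytibolone
T7	b3OHtibolone[e] -> estradiol[c]	Estradiol receptor agonist action mechanism of 3b-hydroxytibolone
T8	d4tibolone[e] -> prgstrn[c] + tststerone[c]	Progesterone and androgen receptor activation by tibolone D4 isomer
T9	a3OHtibolone[e] <=> a3SOtibolone[e]	3a-hydroxytibolone interconversion to sulfated inactive compounds
T10	a3SOtibolone[e] ->	Tibolone inactive form in blood
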