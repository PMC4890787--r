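gene	chrom	start	end
NGFR	chr27	1650100	1668400
PSMC5	chr27	1697500	1705200
SMARCD2	chr27	1706500	1716800
PHB	chr27	1760300	1771200
COL1A1	chr27	3530400	3560700
HOXB7	chr27	3580200	3582700
HOXB8	chr27	3586100	3588600
GIP	chr27	3610800	3618200
ATP6V0A1	chr27	4380200	4420600
KRT222	chr27	4462300	4472900
SMARCE1	chr27	4481000	4493500
CCR7	chr27	4500900	4509800
SP6	chr27	4530100	4540900
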