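subject	execution_auc	execution_psr	execution_nsr	outcome_auc	outcome_psr	outcome_nsr
S01	0.747	60.4	70.4	0.700	17.9	93.6
S02	0.745	54.8	77.6	0.684	6.5	97.4
S03	0.705	49.1	72.5	0.655	19.7	89.4
S04	0.627	15.1	89.9	0.593	0.4	100.0
S05	0.723	49.9	75.8	0.715	12.4	98.2
S06	0.617	44.6	61.2	0.593	3.1	93.1
S07	0.635	15.7	90.6	0.609	0.0	99.9
S08	0.664	35.5	75.3	0.639	4.1	97.6
S09	0.716	58.1	65.9	0.684	13.4	95.9
S10	0.738	58.4	71.4	0.701	9.9	95.8
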