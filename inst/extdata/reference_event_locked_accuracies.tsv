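subject	exec_vs_outcome_T	exec_vs_outcome_F	exec_vs_outcome_TF	outcome_vs_noerror_T	outcome_vs_noerror_F	outcome_vs_noerror_TF	exec_vs_noerror_T	exec_vs_noerror_F	exec_vs_noerror_TF
S01	77.9	69.7	78.7	74.4	75.1	75.1	69.7	68.8	69.6
S02	76.3	73.8	75.7	78.5	66.1	78.5	65.4	62.6	66.4
S03	69.6	66.5	69.6	68.2	79.3	68.2	59.9	59.0	60.1
S04	72.1	62.7	72.7	75.0	63.4	74.4	60.1	60.8	60.7
S05	70.2	65.8	73.7	60.3	68.0	60.2	64.3	61.6	68.9
S06	67.7	65.4	67.7	76.5	76.0	76.5	63.4	65.2	63.4
S07	73.6	80.7	72.9	76.3	83.5	76.3	62.8	63.3	62.0
S08	85.0	73.2	85.4	80.4	86.4	80.4	68.6	67.6	71.6
S09	78.1	69.8	77.3	71.3	76.3	72.1	64.5	66.5	65.0
S10	82.1	78.2	81.5	78.0	81.9	78.8	71.2	66.7	71.8
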