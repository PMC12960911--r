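spot_id	x	y	truth	pred
spot_1	1	1	connective	connective
spot_2	2	1	connective	connective
spot_3	3	1	connective	cancer
spot_4	4	1	connective	cancer
spot_5	5	1	cancer	cancer
spot_6	6	1	cancer	cancer
spot_7	7	1	cancer	cancer
spot_8	8	1	cancer	cancer
spot_9	1	2	connective	connective
spot_10	2	2	connective	connective
spot_11	3	2	connective	cancer
spot_12	4	2	connective	cancer
spot_13	5	2	cancer	cancer
spot_14	6	2	cancer	cancer
spot_15	7	2	cancer	cancer
spot_16	8	2	cancer	cancer
spot_17	1	3	connective	connective
spot_18	2	3	connective	connective
spot_19	3	3	connective	cancer
spot_20	4	3	connective	cancer
spot_21	5	3	cancer	cancer
spot_22	6	3	cancer	cancer
spot_23	7	3	cancer	cancer
spot_24	8	3	cancer	cancer
spot_25	1	4	connective	connective
spot_26	2	4	connective	connective
spot_27	3	4	connective	cancer
spot_28	4	4	connective	cancer
spot_29	5	4	cancer	cancer
spot_30	6	4	cancer	cancer
spot_31	7	4	cancer	cancer
spot_32	8	4	cancer	cancer
spot_33	1	5	connective	connective
spot_34	2	5	connective	connective
spot_35	3	5	connective	cancer
spot_36	4	5	connective	cancer
spot_37	5	5	cancer	cancer
spot_38	6	5	cancer	cancer
spot_39	7	5	cancer	cancer
spot_40	8	5	cancer	cancer
spot_41	1	6	connective	connective
spot_42	2	6	connective	connective
spot_43	3	6	connective	cancer
spot_44	4	6	connective	cancer
spot_45	5	6	cancer	cancer
spot_46	6	6	cancer	cancer
spot_47	7	6	cancer	cancer
spot_48	8	6	cancer	cancer
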