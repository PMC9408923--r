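computed	published	anchored
1_1	1_1	TRUE
2_1	2_1	TRUE
2_2	2_2	TRUE
2_3	2_3	TRUE
3_1	3_1	TRUE
3_2	3_2	TRUE
3_3	3_3	TRUE
3_4	3_4	TRUE
3_5	3_5	TRUE
3_6	3_6	TRUE
3_7	3_7	TRUE
3_8	3_8	TRUE
4_1	4_1	FALSE
4_2	4_2	FALSE
4_3	4_3	FALSE
4_4	4_4	FALSE
4_5	4_5	FALSE
4_6	4_6	FALSE
4_7	4_7	FALSE
4_8	4_8	FALSE
4_9	4_9	FALSE
4_10	4_10	FALSE
4_11	4_11	FALSE
4_12	4_12	FALSE
4_13	4_13	TRUE
4_14	4_14	TRUE
4_15	4_16	TRUE
4_16	4_17	FALSE
4_17	4_18	FALSE
4_18	4_19	TRUE
4_19	4_20	FALSE
4_20	4_21	FALSE
4_21	4_22	FALSE
4_22	4_23	FALSE
4_23	4_24	FALSE
4_24	4_25	FALSE
4_25	4_26	FALSE
4_26	4_27	TRUE
4_27	4_28	FALSE
4_28	4_29	FALSE
4_29	4_30	FALSE
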