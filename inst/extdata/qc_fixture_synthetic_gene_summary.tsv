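gene	category	n_sgrnas	T0vsRef
ESS01	essential_control	11	-5.201
ESS02	essential_control	10	-3.653
ESS03	essential_control	12	-5.863
ESS04	essential_control	4	-5.673
ESS05	essential_control	12	-4.287
ESS06	essential_control	9	-5.114
ESS07	essential_control	5	-3.745
ESS08	essential_control	9	-4.889
ESS09	essential_control	10	-2.649
ESS10	essential_control	4	-4.806
ESS11	essential_control	12	-3.12
ESS12	essential_control	7	-4.776
ESS13	essential_control	4	-2.795
ESS14	essential_control	7	-5.504
ESS15	essential_control	6	-2.731
ESS16	essential_control	3	-5.961
ESS17	essential_control	10	-3.381
ESS18	essential_control	8	-4.742
ESS19	essential_control	12	-5.7
ESS20	essential_control	6	-3.007
ESS21	essential_control	4	-3.529
ESS22	essential_control	8	-2.682
ESS23	essential_control	11	-3.391
ESS24	essential_control	7	-3.703
ESS25	essential_control	4	-3.345
ESS26	essential_control	11	-4.998
ESS27	essential_control	9	-4.605
ESS28	essential_control	6	-3.062
ESS29	essential_control	8	-2.982
ESS30	essential_control	3	-5.165
ESS31	essential_control	10	-4.753
ESS32	essential_control	9	-5.136
ESS33	essential_control	5	-5.188
ESS34	essential_control	5	-5.937
ESS35	essential_control	3	-4.572
ESS36	essential_control	4	-5.613
ESS37	essential_control	10	-4.824
ESS38	essential_control	11	-4.429
ESS39	essential_control	4	-4.161
ESS40	essential_control	5	-2.737
ESS41	essential_control	8	-4.91
ESS42	essential_control	3	-0.289
ESS43	essential_control	10	-0.246
ESS44	essential_control	4	-1.09
ESS45	essential_control	3	-0.819
NON01	nonessential_control	6	-0.395
NON02	nonessential_control	5	0.003
NON03	nonessential_control	4	0.261
NON04	nonessential_control	11	-0.301
NON05	nonessential_control	7	-0.339
NON06	nonessential_control	7	0.562
NON07	nonessential_control	5	-0.361
NON08	nonessential_control	12	0.175
NON09	nonessential_control	4	0.14
NON10	nonessential_control	7	-0.04
NON11	nonessential_control	10	-0.511
NON12	nonessential_control	9	-0.66
NON13	nonessential_control	3	0.199
NON14	nonessential_control	12	-0.752
NON15	nonessential_control	5	-0.073
NON16	nonessential_control	4	-0.107
NON17	nonessential_control	5	-0.575
NON18	nonessential_control	12	-0.586
NON19	nonessential_control	5	-0.106
NON20	nonessential_control	5	-0.648
NON21	nonessential_control	8	0.583
NON22	nonessential_control	3	-0.125
NON23	nonessential_control	6	-0.566
NON24	nonessential_control	9	-0.541
NON25	nonessential_control	12	-0.73
NON26	nonessential_control	10	0.354
NON27	nonessential_control	7	-0.786
NON28	nonessential_control	5	-0.786
NON29	nonessential_control	5	0.054
NON30	nonessential_control	12	-0.439
NON31	nonessential_control	8	0.504
NON32	nonessential_control	4	-0.228
NON33	nonessential_control	8	0.191
NON34	nonessential_control	3	-0.349
NON35	nonessential_control	11	-0.628
NON36	nonessential_control	10	0.269
NON37	nonessential_control	6	-0.271
NON38	nonessential_control	10	-0.841
NON39	nonessential_control	11	-1.355
NON40	nonessential_control	6	-3.142
NON41	nonessential_control	3	-2.523
NON42	nonessential_control	9	-1.296
NON43	nonessential_control	11	-3.439
NON44	nonessential_control	7	-2.988
NON45	nonessential_control	9	-3.407
NON46	nonessential_control	12	-3.343
NON47	nonessential_control	6	-2.778
TGT01	target	12	-0.73
TGT02	target	8	-0.314
TGT03	target	5	0.188
TGT04	target	4	-0.124
TGT05	target	7	-0.629
TGT06	target	10	-0.419
TGT07	target	5	-0.742
TGT08	target	5	-1.069
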