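species_id	genus	family	max_height	leaf_length	leaf_width	flowering_onset	seed_mass	SOS	SSI	BBA	BBO
synsp_001	syngen_01	synfam_01	21.11	5.79	4.83	7	1.062	1	1	0	0
synsp_002	syngen_02	synfam_02	15.35	18.74	5.66	7	7.56	1	1	0	0
synsp_003	syngen_03	synfam_03	12.86	16.82	4.48	5	26.022	1	1	0	0
synsp_004	syngen_04	synfam_04	49.34	9.14	5.08	4	40.848	1	1	0	0
synsp_005	syngen_05	synfam_05	41.86	6.61	12.62	7	13.413	1	1	0	0
synsp_006	syngen_06	synfam_06	7.56	7.55	5.87	5	106.213	1	1	0	0
synsp_007	syngen_07	synfam_07	25.99	8.54	4.27	4	32.765	1	1	0	0
synsp_008	syngen_08	synfam_08	9.58	5.8	2.9	7	3.182	1	1	0	0
synsp_009	syngen_09	synfam_09	11.04	18.73	12.23	4	242.515	1	1	0	0
synsp_010	syngen_10	synfam_10	24.11	8.51	3.07	7	71.762	1	1	0	0
synsp_011	syngen_11	synfam_11	10.56	18.99	7.25	7	104.273	1	1	0	0
synsp_012	syngen_12	synfam_12	23.76	11.22	3.18	5	1.957	1	1	0	0
synsp_013	syngen_13	synfam_13	3.35	7.18	4.6	3	25.623	1	1	0	0
synsp_014	syngen_14	synfam_14	15.8	16.52	5.85	7	369.445	1	1	0	0
synsp_015	syngen_15	synfam_15	2.6	3.27	0.81	5	4.847	1	1	0	0
synsp_016	syngen_16	synfam_16	1.25	2.07	1.41	2	4.914	1	1	0	0
synsp_017	syngen_17	synfam_17	124.12	18.09	3.76	5	201.176	1	1	0	0
synsp_018	syngen_18	synfam_18	8.55	20.34	6.77	5	29.459	1	1	0	0
synsp_019	syngen_19	synfam_19	9.58	4.1	2.96	2	97.052	1	1	0	0
synsp_020	syngen_20	synfam_20	4.48	2.37	3.32	6	16.424	1	1	0	0
synsp_021	syngen_21	synfam_21	10.5	15.6	12.28	7	5.412	1	1	0	0
synsp_022	syngen_22	synfam_22	8.57	9.97	13.54	8	50.171	1	1	0	0
synsp_023	syngen_23	synfam_23	3.8	4.77	1.57	5	16.078	1	1	0	0
synsp_024	syngen_24	synfam_24	3.88	6.78	5.13	7	6.483	1	1	0	0
synsp_025	syngen_25	synfam_25	20.36	43	16.56	3	15.226	1	1	0	0
synsp_026	syngen_26	synfam_26	17.14	4.64	2.37	8	41.691	1	1	0	0
synsp_027	syngen_27	synfam_27	11.99	4.69	7.18	5	141.347	1	1	0	0
synsp_028	syngen_28	synfam_28	6.58	7.43	5.77	6	46.102	1	1	0	0
synsp_029	syngen_29	synfam_29	8.23	1.75	1.42	4	65.142	1	1	0	0
synsp_030	syngen_30	synfam_30	4.36	5.16	4.09	4	3.72	1	1	0	0
synsp_031	syngen_31	synfam_31	5.84	9.67	4.94	5	9.198	1	1	0	0
synsp_032	syngen_32	synfam_32	13.07	8.03	4.45	7	21.919	1	1	0	0
synsp_033	syngen_33	synfam_33	7.79	7.91	3.85	6	27.146	1	1	0	0
synsp_034	syngen_34	synfam_34	10.77	14.74	7.48	4	6.137	1	1	0	0
synsp_035	syngen_35	synfam_35	0.92	2.27	1.14	6	9.318	1	1	0	0
synsp_036	syngen_36	synfam_36	2.17	4.31	2.63	7	0.625	1	1	0	0
synsp_037	syngen_37	synfam_37	49.89	8.98	2.62	6	216.876	1	1	0	0
synsp_038	syngen_38	synfam_38	20.29	3.73	2.01	4	6.425	1	1	0	0
synsp_039	syngen_39	synfam_39	2.45	6.1	4.47	7	237.804	1	1	0	0
synsp_040	syngen_40	synfam_40	57.88	18.97	22.05	5	27.347	1	1	1	0
synsp_041	syngen_41	synfam_41	6.07	5.53	1.77	7	47.26	1	1	1	0
synsp_042	syngen_42	synfam_42	30.11	22.17	8.67	5	72.161	1	1	1	0
synsp_043	syngen_43	synfam_43	18.44	5.31	8.47	5	171.208	1	1	1	0
synsp_044	syngen_44	synfam_44	12.74	5.76	2.33	5	18.545	1	1	1	0
synsp_045	syngen_45	synfam_01	24.64	5.07	3.44	7	120.683	1	1	1	0
synsp_046	syngen_46	synfam_02	4.59	14.51	4.2	4	34.77	1	1	1	0
synsp_047	syngen_47	synfam_03	6.16	4.22	1.6	7	24.615	1	1	1	0
synsp_048	syngen_48	synfam_04	3.83	3.84	4.34	6	42.955	1	1	1	0
synsp_049	syngen_49	synfam_05	18.16	15.21	4.85	7	5.945	1	1	1	0
synsp_050	syngen_50	synfam_06	14.59	5.88	4.48	5	103.729	1	1	1	0
synsp_051	syngen_51	synfam_07	3.45	4.1	2.88	7	64.393	1	1	1	0
synsp_052	syngen_52	synfam_08	25.25	5.09	5.48	4	136.577	1	1	1	0
synsp_053	syngen_53	synfam_09	10.78	3.99	3.11	6	59.2	1	1	1	0
synsp_054	syngen_54	synfam_10	8.98	6.58	2.94	5	48.624	1	1	1	0
synsp_055	syngen_55	synfam_11	14.82	6.22	2.61	7	45.155	1	1	1	1
synsp_056	syngen_56	synfam_12	12.06	10.43	4.63	6	339.439	1	1	1	1
synsp_057	syngen_57	synfam_13	5.33	2.89	1.8	4	22.736	1	1	1	1
synsp_058	syngen_58	synfam_14	20.5	6.94	1.77	2	4.302	1	1	1	1
synsp_059	syngen_59	synfam_15	4.91	9.91	2.98	6	6.223	1	1	1	1
synsp_060	syngen_60	synfam_16	32.92	6.59	3.53	4	1593.441	1	1	1	1
synsp_061	syngen_61	synfam_17	17.77	11.29	4.39	5	5.923	1	0	1	1
synsp_062	syngen_62	synfam_18	2.99	7.48	6.24	7	3.143	1	0	1	1
synsp_063	syngen_63	synfam_19	11.16	5.92	2.51	6	244.239	1	0	1	1
synsp_064	syngen_64	synfam_20	14.55	10.12	6.11	8	10.872	1	0	1	1
synsp_065	syngen_65	synfam_21	2.39	6.47	2.06	6	93.677	1	0	1	1
synsp_066	syngen_66	synfam_22	2.74	6.37	6.93	8	29.228	1	0	1	1
synsp_067	syngen_67	synfam_23	7.89	6.81	5.22	6	63.081	1	0	1	1
synsp_068	syngen_68	synfam_24	4.3	4.92	1.35	3	3.228	1	0	1	1
synsp_069	syngen_69	synfam_25	56.47	7.43	3.75	8	228.937	1	0	1	1
synsp_070	syngen_70	synfam_26	5.72	6.9	3.76	9	4.459	1	0	1	1
synsp_071	syngen_71	synfam_27	23.34	16.99	8.46	7	795.778	1	0	1	1
synsp_072	syngen_72	synfam_28	4.41	6.64	8.81	7	4.649	1	0	1	1
synsp_073	syngen_73	synfam_29	19.1	13.74	11.55	6	5.535	0	0	1	1
synsp_074	syngen_01	synfam_01	9.87	6.95	3.07	7	18.691	0	0	1	1
synsp_075	syngen_02	synfam_02	4.31	3.4	1.36	5	5.231	0	0	1	1
synsp_076	syngen_03	synfam_03	5.28	2.8	1.72	5	5.402	0	0	1	1
synsp_077	syngen_04	synfam_04	29.25	3.55	2.43	4	9.035	0	0	1	1
synsp_078	syngen_05	synfam_05	24.9	8	8.73	6	57.004	0	0	1	1
synsp_079	syngen_06	synfam_06	9.94	3.98	3.27	5	207.102	0	0	1	1
synsp_080	syngen_07	synfam_07	14.65	8.99	1.65	7	31.126	0	0	1	1
synsp_081	syngen_08	synfam_08	57.29	8.72	3.4	7	60.733	0	0	1	1
synsp_082	syngen_09	synfam_09	9.15	8.97	5.2	6	474.514	0	0	1	1
synsp_083	syngen_10	synfam_10	7.14	13.43	3.73	5	2.83	0	0	1	1
synsp_084	syngen_11	synfam_11	46.76	18.42	4.66	5	22.197	0	0	1	1
synsp_085	syngen_12	synfam_12	28.95	15.08	6.41	7	10.285	0	0	1	1
synsp_086	syngen_13	synfam_13	17.33	5.41	5.08	7	19.694	0	0	1	1
synsp_087	syngen_14	synfam_14	1.82	2.89	1.35	6	2.583	0	0	1	1
synsp_088	syngen_15	synfam_15	14.77	6.6	2.84	5	42.87	0	0	1	1
synsp_089	syngen_16	synfam_16	17.86	45.19	11.37	7	38.808	0	0	1	1
synsp_090	syngen_17	synfam_17	6.91	5.32	1.87	6	9.152	0	0	1	1
synsp_091	syngen_18	synfam_18	14.39	40.55	26.71	5	26.93	0	0	1	1
synsp_092	syngen_19	synfam_19	4.37	10.46	2.65	6	3.806	0	0	1	1
synsp_093	syngen_20	synfam_20	19.57	14.84	4.8	5	36.844	0	0	1	1
synsp_094	syngen_21	synfam_21	2.62	3.1	1.28	4	10.256	0	0	1	1
synsp_095	syngen_22	synfam_22	24.71	3.26	3.98	5	41.988	0	0	1	1
synsp_096	syngen_23	synfam_23	67.08	31.17	5.08	4	53.138	0	1	1	1
synsp_097	syngen_24	synfam_24	12.53	5.02	3.83	3	6.035	0	1	1	1
synsp_098	syngen_25	synfam_25	38.84	11.43	4.73	5	16.019	0	1	1	1
synsp_099	syngen_26	synfam_26	18.47	15.89	2.94	4	22.362	0	1	1	1
synsp_100	syngen_27	synfam_27	27.77	6.28	3	8	5.265	0	1	1	1
synsp_101	syngen_28	synfam_28	5.66	11.88	4.93	5	31.55	0	1	1	1
synsp_102	syngen_29	synfam_29	7.04	7.04	2.19	6	2.197	0	1	1	1
synsp_103	syngen_30	synfam_30	3.67	23.36	3.64	5	8.377	0	1	1	1
synsp_104	syngen_31	synfam_31	10.61	14.82	8.04	4	9.271	0	1	1	1
synsp_105	syngen_32	synfam_32	19.76	6.92	4.31	10	2.356	0	1	1	1
synsp_106	syngen_33	synfam_33	0.72	6.13	2.95	7	4.442	0	1	0	1
synsp_107	syngen_34	synfam_34	9.13	16.06	8.25	6	105.498	0	1	0	1
synsp_108	syngen_35	synfam_35	7.54	14.88	4.45	5	30.439	0	1	0	1
synsp_109	syngen_36	synfam_36	3.51	6.86	3.45	5	143.182	0	1	0	1
synsp_110	syngen_37	synfam_37	66.97	22.96	13.02	5	62.128	0	1	0	1
synsp_111	syngen_38	synfam_38	6.07	8.01	5.77	5	56.047	0	1	0	1
synsp_112	syngen_39	synfam_39	1.87	5.25	3.19	6	1.834	0	1	0	1
synsp_113	syngen_40	synfam_40	3.49	4	3	5	135.401	0	1	0	0
synsp_114	syngen_41	synfam_41	4.95	7.73	9.35	5	6.928	0	1	0	0
synsp_115	syngen_42	synfam_42	1.57	3.69	3.42	5	158.55	0	1	0	0
synsp_116	syngen_43	synfam_43	5.36	13.79	6.51	8	46.147	0	1	0	0
synsp_117	syngen_44	synfam_44	3.86	3.35	4.36	4	13.442	0	1	0	0
synsp_118	syngen_45	synfam_01	16.32	5.35	3.65	5	35.585	0	1	0	0
synsp_119	syngen_46	synfam_02	28.86	10.25	6.06	4	259.572	0	1	0	0
synsp_120	syngen_47	synfam_03	5.89	6.92	3.28	5	10.525	0	1	0	0
synsp_121	syngen_48	synfam_04	4.76	4.62	3.95	4	153.877	0	1	0	0
synsp_122	syngen_49	synfam_05	13.09	4.24	2.78	3	149.69	0	1	0	0
synsp_123	syngen_50	synfam_06	16.28	6.6	3.09	5	144.022	0	1	0	0
synsp_124	syngen_51	synfam_07	3.94	6.49	2.59	8	2.92	0	1	0	0
synsp_125	syngen_52	synfam_08	3.81	13.86	2.61	4	53.846	0	1	0	0
synsp_126	syngen_53	synfam_09	15.08	10.21	9.97	6	18.584	0	1	0	0
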