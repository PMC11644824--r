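no	name	logp	formula	rt	adduct	mz_calc	mz_meas	error_ppm	skeleton_class	flag
1	5-Hydroxy-7-{{6-O-{[(4R/S)-4-(1-hydroxy-1-methylethyl)cyclohex-1-en-1-yl]-carbonyl}-D-glucopyranosyl}oxy}-2-methyl-4H-1-benzopyran-4-one	2.83	C_26_H_32_O_11_	7.39	[M+H]+	521.2017	521.2045	-5.3	other
1	5-Hydroxy-7-{{6-O-{[(4R/S)-4-(1-hydroxy-1-methylethyl)cyclohex-1-en-1-yl]-carbonyl}-D-glucopyranosyl}oxy}-2-methyl-4H-1-benzopyran-4-one	2.83	C_26_H_32_O_11_	7.39	[M+Na]+	543.1837	543.1867	-5.5	other
2	11-Oxooleanolic acid	6.78	C_30_H_46_O_4_	9.76	[M+H]+	471.3469	471.349	-4.5	oleanane
3	Asiatic acid	6.46	C_30_H_48_O_5_	9.8	[M+H]+	489.3575	489.356	2.9	ursane
3	Asiatic acid	6.46	C_30_H_48_O_5_	9.8	[M+Na]+	511.3394	511.339	0.8	ursane
4	Euscaphic acid	6.21	C_30_H_48_O_5_	9.11	[M+H]+	489.3575	489.356	2.9	ursane
4	Euscaphic acid	6.21	C_30_H_48_O_5_	9.11	[M+Na]+	511.3394	511.338	2.6	ursane
5	Silymin A	4.92	C_30_H_44_O_5_	9.9	[M+H]+	485.3262	485.3249	2.6	oleanane
5	Silymin A	4.92	C_30_H_44_O_5_	9.9	[M+Na]+	507.3081	507.3038	8.4	oleanane
6	beta-Neriursate	11.47	C_38_H_54_O_4_	10.35	[M+H]+	575.4095	575.4124	-5.1	ursane
7	3beta-Hydroxy-27-p-E-coumaroyloxy-urs-12-en-28-oic acid	9.47	C_39_H_54_O_6_	10.02	[M+H]+	619.3993	619.3984	1.5	ursane
7	3beta-Hydroxy-27-p-E-coumaroyloxy-urs-12-en-28-oic acid	9.47	C_39_H_54_O_6_	10.02	[M+Na]+	641.3813	641.3800	2.0	ursane
8	Ilelatifol D	6.29	C_30_H_46_O_4_	9.11	[M+H]+	471.3469	471.3455	2.9	ursane
9	Glycyrrhetic acid	6.57	C_30_H_46_O_4_	9.86	[M+H]+	471.3469	471.3465	0.8	oleanane
10	Bellerigenin B	3.65	C_30_H_48_O_7_	8.84	[M+H]+	521.3473	521.3466	1.3	oleanane
10	Bellerigenin B	3.65	C_30_H_48_O_7_	8.84	[M+Na]+	543.3292	543.3287	1	oleanane
11	Intybusoloid	2.24	C_27_H_34_O_8_	8.83	[M+H]+	487.2326	487.2322	0.9	limonoid
11	Intybusoloid	2.24	C_27_H_34_O_8_	8.83	[M+Na]+	509.2146	509.2141	1	limonoid
12	Ursolaldehyde	9.14	C_30_H_48_O_2_	11.43	[M+H]+	441.3727	441.3711	3.7	ursane
12	Ursolaldehyde	9.14	C_30_H_48_O_2_	11.43	[M+Na]+	463.3547	463.3536	2.3	ursane
13	Hydrazide of glycyrrhetinic acid	5.28	C_32_H_50_N_2_O_5_	9.63	[M+H]+	543.3792	543.3769	4.4	oleanane
13	Hydrazide of glycyrrhetinic acid	5.28	C_32_H_50_N_2_O_5_	9.63	[M+Na]+	565.3612	565.3586	4.5	oleanane
14	Ethyl methyl sulfide ester of betulinic acid	10.27	C_33_H_54_O_3_S_1_	10.36	[M+H]+	531.3866	531.3863	0.6	lupane
15	2,3,23-Triacetoxy derivative of asiatic acid	8.59	C_36_H_54_O_8_	10.19	[M+H]+	615.3891	615.3878	2.2	ursane
15	2,3,23-Triacetoxy derivative of asiatic acid	8.59	C_36_H_54_O_8_	10.19	[M+Na]+	637.3711	637.3695	2.5	ursane
16	Betulinic acid	8.94	C_30_H_48_O_3_	10.58	[M+H]+	457.3676	457.3664	2.6	lupane
16	Betulinic acid	8.94	C_30_H_48_O_3_	10.58	[M+Na]+	479.3496	479.3473	4.7	lupane
17	Betulin	9.01	C_30_H_50_O_2_	10.35	[M+H]+	443.3884	443.3858	5.7	lupane
17	Betulin	9.01	C_30_H_50_O_2_	10.35	[M+Na]+	465.3703	465.3690	2.8	lupane
18	Lantanilic acid	8.37	C_35_H_52_O_6_	10.43	[M+H]+	569.3837	569.3827	1.7	oleanane
18	Lantanilic acid	8.37	C_35_H_52_O_6_	10.43	[M+Na]+	591.3656	591.3669	-2.1	oleanane
19	3-Benzoyloxy-3-O-methyl ester of glycyrrhetinic acid	9.91	C_38_H_52_O_5_	10.89	[M+H]+	589.3888	589.3866	3.7	oleanane
19	3-Benzoyloxy-3-O-methyl ester of glycyrrhetinic acid	9.91	C_38_H_52_O_5_	10.89	[M+Na]+	611.3707	611.3697	1.6	oleanane
20	Methyl acetate ester of betulinic acid	9.50	C_33_H_52_O_5_	10.87	[M+H]+	529.3888	529.3902	-2.6	lupane
20	Methyl acetate ester of betulinic acid	9.50	C_33_H_52_O_5_	10.87	[M+Na]+	551.3707	551.3721	-2.5	lupane
21	Azadiradione	4.21	C_28_H_34_O_5_	8.54	[M+H]+	451.2479	451.2486	-1.5	limonoid
21	Azadiradione	4.21	C_28_H_34_O_5_	8.54	[M+Na]+	473.2298	473.2306	-1.6	limonoid
22	Gedunin	3.34	C_28_H_34_O_7_	8.82	[M+H]+	483.2377	483.2388	-2.2	limonoid
22	Gedunin	3.34	C_28_H_34_O_7_	8.82	[M+Na]+	505.2197	505.2206	-1.9	limonoid
23	Ethyl acetate ester of glycyrrhetinic acid	7.63	C_34_H_52_O_6_	10.33	[M+H]+	557.3837	557.3845	-1.6	oleanane
23	Ethyl acetate ester of glycyrrhetinic acid	7.63	C_34_H_52_O_6_	10.33	[M+Na]+	579.3656	579.3665	-1.5	oleanane
24	Oleanolic acid	9.06	C_30_H_48_O_3_	10.51	[M+H]+	457.3676	457.3654	4.8	oleanane
24	Oleanolic acid	9.06	C_30_H_48_O_3_	10.51	[M+Na]+	479.3496	479.3504	-1.7	oleanane
25	3-Oxo-30-butyl ester of glycyrrhetinic acid	8.35	C_34_H_52_O_4_	10.94	[M+H]+	525.3938	525.3952	-2.7	oleanane
25	3-Oxo-30-butyl ester of glycyrrhetinic acid	8.35	C_34_H_52_O_4_	10.94	[M+Na]+	547.3758	547.3772	-2.5	oleanane
26	beta-Amyrin	11.06	C_30_H_50_O	10.50	[M+H]+	427.3934	427.3920	3.3	oleanane
26	beta-Amyrin	11.06	C_30_H_50_O	10.50	[M+Na]+	449.3754	449.3730	5.3	oleanane
27	Diethyl sulfide ester of betulinic acid	10.80	C_34_H_56_O_3_S_1_	10.69	[M+H]+	545.4023	545.403	-1.3	lupane
28	Nimbinolide	0.71	C_30_H_36_O_11_	7.51	[M+H]+	573.233	573.232	1.8	limonoid
28	Nimbinolide	0.71	C_30_H_36_O_11_	7.51	[M+Na]+	595.215	595.2139	-1.8	limonoid
29	Ursonic acid	8.43	C_30_H_46_O_3_	10.81	[M+H]+	455.3520	455.3512	1.7	ursane
29	Ursonic acid	8.43	C_30_H_46_O_3_	10.81	[M+Na]+	477.3339	477.3333	1.4	ursane
30	3-Acetoxy-3-O-methyl ester of glycyrrhetinic acid	7.89	C_33_H_50_O_5_	10.88	[M+H]+	527.3731	527.3722	1.7	oleanane
30	3-Acetoxy-3-O-methyl ester of glycyrrhetinic acid	7.89	C_33_H_50_O_5_	10.88	[M+Na]+	549.355	549.3542	1.5	oleanane
31	3,25-Epoxy-3alpha-hydroxy-olean-12-en-28-oic acid	7.29	C_30_H_46_O_4_	10.62	[M+H]+	471.3469	471.3451	3.8	oleanane
31	3,25-Epoxy-3alpha-hydroxy-olean-12-en-28-oic acid	7.29	C_30_H_46_O_4_	10.62	[M+Na]+	493.3288	493.3286	0.5	oleanane
32	Butyl ester of glycyrrhetinic acid	8.59	C_34_H_54_O_4_	10.89	[M+H]+	527.4095	527.4097	-0.4	oleanane
32	Butyl ester of glycyrrhetinic acid	8.59	C_34_H_54_O_4_	10.89	[M+Na]+	549.3914	549.3917	-0.5	oleanane
33	Methyl acetate ester of glycyrrhetinic acid	7.10	C_33_H_50_O_6_	10.2	[M+H]+	543.368	543.3683	-0.6	oleanane
33	Methyl acetate ester of glycyrrhetinic acid	7.10	C_33_H_50_O_6_	10.2	[M+Na]+	565.35	565.3502	-0.5	oleanane
34	Glycyrrhetinic acid methyl ester	7.00	C_31_H_48_O_4_	10.32	[M+H]+	485.3625	485.3615	2.1	oleanane
34	Glycyrrhetinic acid methyl ester	7.00	C_31_H_48_O_4_	10.32	[M+Na]+	507.3445	507.3446	-0.3	oleanane
35	Diethyl sulfide ester of ursolic acid	10.87	C_34_H_56_O_3_S_1_	10.58	[M+H]+	545.4023	545.4021	0.3	ursane
36	Oleanoic acid	8.48	C_30_H_46_O_3_	10.79	[M+H]+	457.3676	457.3635	8.9	oleanane	calc_inconsistent
36	Oleanoic acid	8.48	C_30_H_46_O_3_	10.79	[M+Na]+	477.3339	477.334	-0.2	oleanane
37	Methyl acetate ester of oleanolic acid	9.62	C_33_H_52_O_5_	10.93	[M+Na]+	551.3707	551.3708	-0.2	oleanane
38	3-Oxolup-1:12-diene, 28-al	8.05	C_30_H_44_O_2_	10.56	[M+Na]+	459.3234	459.3279	-10	lupane
39	3beta-Hydroxyurs-11-en-13b(28)-olide	7.48	C_30_H_46_O_3_	10.53	[M+H]+	455.352	455.3539	0.6	ursane
39	3beta-Hydroxyurs-11-en-13b(28)-olide	7.48	C_30_H_46_O_3_	10.53	[M+Na]+	477.3339	477.3315	5.0	ursane
40	2alpha-Hydroxyursolic acid	7.82	C_30_H_48_O_4_	10.1	[M+H]+	473.3625	473.3615	2.1	ursane
40	2alpha-Hydroxyursolic acid	7.82	C_30_H_48_O_4_	10.1	[M+Na]+	495.3445	495.3486	-8.2	ursane
41	Friedelin	10.87	C_30_H_50_O	10.60	[M+H]+	427.3934	427.3926	1.8	friedelane
41	Friedelin	10.87	C_30_H_50_O	10.60	[M+Na]+	449.3754	449.3740	3.1	friedelane
42	Ursolic acid	9.01	C_30_H_48_O_3_	10.7	[M+H]+	457.3676	457.3659	3.7	ursane
42	Ursolic acid	9.01	C_30_H_48_O_3_	10.7	[M+Na]+	479.3496	479.3459	7.7	ursane
43	Atriplicin	7.06	C_30_H_46_O_4_	9.8	[M+H]+	471.3469	471.3451	3.8	ursane
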