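name	type	sp_len	target	mature_len	mass_da	pi	intron_count	intron_positions	ortholog
BoLTP1.1	1	24	s	95	9922.37	7.40	1	5	AT3G51590
BoLTP1.2	1	25	s	91	9394.83	10.13	0		AT3G51600
BoLTP1.3	1	24	s	92	9310.59	7.71	1	5	AT2G18370
BoLTP1.4	1	25	s	91	9682.25	11.42	0		AT3G51600
BoLTP1.5	1	19	s	92	9549.78	8.51	0		AT3G08770
BoLTP1.6	1	25	s	91	9693.23	11.27	0		AT3G51590
BoLTP1.7	1	24	s	90	9498.97	8.19	0		AT3G51590
BoLTP1.8	1	23	s	92	9175.57	8.49	1	5	AT5G59320
BoLTP1.9	1	23	s	87	8723.11	8.70	0		AT5G59310
BoLTP1.10	1	26	s	136	14404.74	9.13	1	5	AT4G33355
BoLTP1.11	1	18	s	116	11905.88	9.37	0		AT2G38540
BoLTP1.12	1	22	s	96	10212.54	3.63	0		AT5G62065
BoLTP1.13	1	25	s	94	9590.03	9.08	0		AT2G38530
BoLTP1.14	1	25	s	94	9590.03	9.08	0		AT2G38530
BoLTP1.15	1	25	s	94	9520.92	8.91	0		AT2G38540
BoLTP1.16	1	23	s	100	10493.99	8.70	1	5	AT5G59320
BoLTP1.17	1	23	s	87	8792.32	9.03	0		
BoLTP1.18	1	21	s	97	10061.41	7.69	1	5	AT4G33355
BoLTP1.19	1	20	s	93	9648.84	8.73	0		AT3G08770
BoLTP2.1	2	28	s	68	7411.84	9.75	0		AT3G18280
BoLTP2.2	2	20	s	76	7716.91	8.20	0		AT1G66850
BoLTP2.3	2	29	s	68	7143.28	8.90	0		AT1G48750
BoLTP2.4	2	28	s	68	7381.78	9.54	0		AT3G18280
BoLTP2.5	2	24	s	73	7877.10	4.80	0		AT3G57310
BoLTP2.6	2	30	s	67	7636.89	8.17	0		AT1G73780
BoLTP2.7	2	28	s	68	7460.87	9.94	0		AT3G18280
BoLTP2.8	2	30	s	68	7645.89	8.42	0		AT1G73780
BoLTP2.9	2	24	s	78	8524.93	5.18	0		AT5G38195
BoLTP2.10	2	24	s	75	7792.09	7.44	0		
BoLTP2.11	2	29	s	68	7255.47	9.06	0		AT1G48750
BoLTP2.12	2	21	s	74	7647.76	7.71	0		AT1G66850
BoLTPc1	C	34	s	64	6729.72	6.71	0		AT5G52160
BoLTPd1	D	23	s	78	8281.64	8.19	0		
BoLTPd2	D	19	s	89	9521.31	9.15	1	4	AT4G30880
BoLTPd3	D	28	s	87	9234.97	9.30	0		
BoLTPd4	D	28	s	86	9285.70	8.86	1	4	AT4G33550
BoLTPd5	D	23	s	92	9521.52	10.48	1	4	AT2G37870
BoLTPd6	D	19	s	90	9607.40	8.71	1	4	AT4G30880
BoLTPd7	D	28	s	84	8910.50	8.72	0		AT5G55450
BoLTPd8	D	28	s	87	9204.80	8.50	0		AT5G55450
BoLTPd9	D	28	s	90	9616.54	9.06	1	4	AT5G55450
BoLTPd10	D	23	s	78	8348.74	8.68	0		
BoLTPd11	D	23	s	92	9517.49	10.42	1	4	AT2G37870
BoLTPd12	D	26	s	73	7445.50	4.46	0		AT5G55450
BoLTPd13	D	30	s	89	9707.56	8.80	0		AT5G55450
BoLTPd14	D	26	s	73	7521.59	4.46	0		
BoLTPd15	D	27	s	76	8139.38	5.04	0		AT5G48490
BoLTPd16	D	28	s	79	8381.89	9.03	1	4	AT5G55410
BoLTPd17	D	28	s	74	7756.12	8.88	0		AT5G55410
BoLTPd18	D	23	s	91	9356.81	8.70	1	4	AT3G53980
BoLTPe1	E	24	c	97	10408.26	4.72	0		AT3G52130
BoLTPe2	E	25	s	97	10290.02	4.72	0		AT3G52130
BoLTPg1	G	21	s	173	17684.24	5.64	1	4	AT1G27950
BoLTPg2	G	22	s	185	18970.72	8.45	2	1,155	AT4G08670
BoLTPg3	G	22	c	181	18590.24	7.70	2	1,134	
BoLTPg4	G	21	s	174	17641.27	6.11	1	4	AT1G27950
BoLTPg5	G	17	s	173	17386.80	4.31	2	4,926	AT3G43720
BoLTPg6	G	19	s	285	29369.39	4.70	2	1,147	AT1G36150
BoLTPg7	G	19	s	160	15708.96	8.14	2	19,167	AT1G18280
BoLTPg8	G	22	s	136	13860.91	5.59	1	19	AT1G18280
BoLTPg9	G	22	s	160	15697.94	7.73	2	19,167	AT1G18280
BoLTPg10	G	31	s	157	16414.03	4.68	1	19	AT4G22666
BoLTPg11	G	25	s	124	12877.69	6.30	2	4,126	AT1G62790
BoLTPg12	G	24	s	147	14871.51	5.05	2	7,140	AT3G22600
BoLTPg13	G	20	s	155	15572.72	6.07	2	-5,40	AT1G18280
BoLTPg14	G	19	s	190	19568.39	5.19	1	1	AT1G36150
BoLTPg15	G	26	s	178	18208.64	4.34	4	4,164,371,617	AT1G05450
BoLTPg16	G	25	s	154	15227.71	7.11	2	4,211	
BoLTPg17	G	24	s	148	14812.25	8.48	2	4,289	
BoLTPg18	G	22	s	90	9701.35	6.99	1	13	AT1G73560
BoLTPg19	G	21	s	116	12333.19	5.42	1	7	AT1G73550
BoLTPg20	G	23	s	182	18472.01	4.99	1	31	AT3G22620
BoLTPg21	G	26	s	162	16361.87	8.73	2	7,188	AT1G73890
BoLTPg22	G	22	s	158	15803.06	6.93	2	13,173	AT1G18280
BoLTPg23	G	21	s	127	13708.39	4.18	2	13,193	AT1G73550
BoLTPg24	G	22	s	127	13220.35	5.62	2	13,163	AT1G73560
BoLTPg25	G	26	s	175	17570.14	5.66	2	4,173,410,623	AT1G05450
BoLTPg26	G	22	c	179	18303.98	8.45	2	1,131	
BoLTPg27	G	21	s	174	17769.26	6.90	1	4	AT1G27950
BoLTPg28	G	27	s	147	14350.26	4.69	2	4,126	AT2G13820
BoLTPx1	X	25	s	99	10667.26	4.57	0		
BoLTPx2	X	22	s	95	10049.59	8.15	0		
BoLTPx3	X	23	s	118	13635.59	5.76	1	1	AT1G52415
BoLTPx4	X	24	s	76	8355.81	8.70	0		AT1G64235
BoLTPx5	X	24	s	68	7128.46	9.05	0		AT1G64235
BoLTPx6	X	22	s	92	10068.84	8.68	0		AT4G08530
BoLTPx7	X	28	s	106	11759.57	6.09	1	12	
BoLTPx8	X	24	s	96	10034.94	7.67	0		
BoLTPx9	X	21	s	101	10653.27	7.71	0		
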