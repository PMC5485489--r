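protein	cp01	cp02	cp03	cp04	cp05	cp06	cp07	cp08	cp09	cp10	cp11	cp12	cp13	cp14	cp15	cp16	cp17	cp18	cp19	cp20	cp21	cp22	cp23	cp24	cp25	cp26	cp27	cp28	cp29	cp30	cp31	cp32	cp33	cp34	cp35	cp36	cp37	cp38	cp39
P01	1.371	2.0184	-0.2843	1.8952	1.0351	0.206	-0.4314	0.6793	-0.7273	0.6235	1.5127	0.9333	-1.1317	-0.6668	-0.4854	-1.4936	-1.2247	-0.1173	-0.4139	1.1672	-0.1755	0.0849	-1.449	-0.2793	0.2526	-2.0009	-0.6457	-0.1321	0.4284	-1.2016	-0.7292	0.7036	-0.7384	-0.054	0.1574	0.8241	-2.1132	-0.1663	-0.1465
P02	-0.5647	-0.0627	-2.6565	-0.4305	-0.6089	-0.3611	0.6556	0.0898	1.3025	-0.9535	0.2579	0.8218	-1.4592	0.1055	-0.5042	-1.4704	0.1795	1.2015	1.1134	-0.2736	-1.0718	0.8956	0.643	-1.3362	-1.294	0.3338	-0.1854	1.4768	-0.174	-0.4661	0.9981	-0.9714	0.0466	1.0648	0.4316	-1.6626	0.2737	0.8626	-0.0579
P03	0.3631	1.3049	-2.4405	-0.2573	0.505	0.7582	0.3219	-2.9931	0.3358	-0.5428	0.0884	1.3921	0.08	-0.4223	-1.6611	0.1247	0.5676	-0.4697	-0.481	-0.4678	0.1632	-0.2298	0.4832	0.7007	-0.9592	1.1713	-1.2012	-0.217	0.5157	-0.2694	1.2585	-1.0962	-1.0176	0.8132	-0.3965	-0.5693	-0.6876	0.0973	0.4824
P04	0.6329	2.2866	1.3201	-1.7632	-1.717	-0.7267	-0.7838	0.2849	1.0385	0.581	-0.1209	-0.4762	0.6532	-0.1224	-0.3823	-0.9966	-0.4929	-0.0525	-0.4332	-1.2383	-0.3627	0.8366	-0.0064	0.5542	1.0858	2.0595	2.037	-1.2836	-0.2344	-0.391	1.2489	0.0491	-0.3833	-0.1908	1.31	0.6355	0.446	-1.6256	0.9929
P05	0.4043	-1.3889	-0.3066	0.4601	-0.7845	-1.3683	1.5757	-0.3672	0.9207	0.7682	-1.1943	0.6503	1.201	0.1882	-0.5127	-0.0018	1e-4	-0.0861	0.6969	-0.0078	0.59	-1.7451	0.1515	-0.8363	0.4038	-1.3769	0.10780000000000001	0.3857	-0.6585	1.3487	-1.3806	-1.1985	0.8728	-2.6999	0.4704	0.0437	-0.8124	-0.0046	-1.2464
T1	1.8939	1.7212	0.2187	1.36	1.1491	0.4328	0.6429	0.1852	0.7209	0.4638	0.612	1.3911	1.0448	0.1192	2.7019	-0.4283	1.1229	-0.8877	-1.0564	-0.8003	1.4324	1.6895	-0.5841	-1.5946	0.5865	-1.1509	-0.0841	-0.3515	1.2502	-0.0228	2.05	0.19	0.9695	0.061	-1.2427	0.348	2.2121	0.7602	-0.0335
T2	3.5115	1.8667	1.8281	2.4555	-0.4142	-0.8114	0.0898	0.5818	-1.0431	-0.8858	-0.2171	-1.1108	-1.0032	-0.0251	-1.3621	-0.6137	1.4399	-0.4447	-0.0407	-0.5335	-0.9927	0.8648	0.3688	0.205	1.8152	-0.7058	0.4956	-0.5218	-0.2718	0.2442	1.0169	1.2977	0.3838	0.5738	1.3816	2.4596	-0.1237	0.039	-0.071
T3	1.9053	2.636	3.2147	2.7048	2.0361	1.4441	0.2766	1.3997	-0.0902	-1.0998000000000001	-0.1828	-0.8608	1.8485	0.1081	0.1373	-2.0247	-1.0971	-0.0294	-1.5515	1.2877	0.4547	-0.1508	0.2947	-0.3451	0.1288	-1.0541	0.0374	-1.0681	0.948	-0.9424	-0.0267	-1.0339	-1.8516	0.0458	1.2045	-0.8184	-0.4773	0.7351	-0.7589
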