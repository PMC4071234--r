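terminal	protein_length	n_tmd	type_label	score	override
Aco001931	654	9	Long	1	FALSE
Aco007499	356	9	Short	2	FALSE
Aco016169	620	9	Long	1	FALSE
Aco018139	641	9	Long	1	FALSE
Aco018694	612	5	Long	1	TRUE
AtPIN1	622	9	Long	1	FALSE
AtPIN2	647	9	Long	1	FALSE
AtPIN3	640	9	Long	1	FALSE
AtPIN4	616	10	Long	1	FALSE
AtPIN5	351	9	Short	2	FALSE
AtPIN6	570	9	Reduced	3	FALSE
AtPIN7	619	9	Long	1	FALSE
AtPIN8	367	8	Short	2	FALSE
Csi_g006199	657	10	Long	1	FALSE
Csi_g007420	604	8	Long	1	FALSE
Csi_g007826	588	8	Long	1	FALSE
Csi_g018360	357	8	Short	2	FALSE
Csi_g019021	347	9	Short	2	FALSE
Csi_g035534	291	5	N-terminal TMD only	5	FALSE
Csi_g036474	646	9	Long	1	FALSE
Csi_g041301	291	7	Short	2	FALSE
Csi_g048649	256	5	N-terminal TMD only	5	FALSE
EgrA02229_1	599	8	Long	1	FALSE
EgrB00948_1	587	9	Long	1	FALSE
EgrB01403_1	365	9	Short	2	FALSE
EgrB01405_1	364	9	Short	2	FALSE
EgrB01406_1	285	7	Short	2	FALSE
EgrB02902_1	657	9	Long	1	FALSE
EgrC00078_1	626	9	Long	1	FALSE
EgrF04265_1	530	8	Reduced	3	FALSE
EgrG02187_1	652	9	Long	1	FALSE
EgrG02548_1	338	9	Short	2	FALSE
EgrG02549_1	360	9	Short	2	FALSE
EgrH01382_1	262	6	Short	2	FALSE
EgrH01390_1	519	7	Long	1	FALSE
EgrI01919_1	356	8	Short	2	FALSE
EgrK02271_1	598	9	Long	1	FALSE
Mes003367	646	9	Long	1	FALSE
Mes003794	614	8	Long	1	FALSE
Mes003807	614	8	Long	1	FALSE
Mes006998	468	9	Long	1	FALSE
Mes010607	357	9	Short	2	FALSE
Mes010688	354	9	Short	2	FALSE
Mes026579	598	7	Long	1	FALSE
Mes029063	361	8	Short	2	FALSE
Mes029078	626	9	Long	1	FALSE
Mes030090	380	5	N-terminal TMD only	5	FALSE
Mes033391	355	8	Short	2	FALSE
Mtr2g043210	315	4	N-terminal TMD only	5	FALSE
Mtr4g154810	524	8	Long	1	FALSE
Mtr6g083450	659	10	Long	1	FALSE
Mtr7g008720	357	8	Short	2	FALSE
Mtr7g089430	363	9	Short	2	FALSE
Mtr7g106430	591	8	Long	1	FALSE
Mtr8g130020	625	9	Long	1	FALSE
Mtr8g130040	568	10	Long	1	FALSE
Mtr4g084870	659	10	Long	1	FALSE
MtrAAT48627	527	9	Long	1	FALSE
MtrAY115838	621	10	Long	1	FALSE
OsPIN1a	595	10	Long	1	FALSE
OsPIN1b	554	9	Reduced	3	FALSE
OsPIN1c	592	10	Long	1	FALSE
OsPIN1d	390	4	C-terminal TMD only	4	FALSE
OsPIN2	630	9	Long	1	FALSE
OsPIN3a	670	5	Long	1	TRUE
OsPIN3b	591	10	Long	1	FALSE
OsPIN5a	363	7	Short	2	FALSE
OsPIN5b	398	7	Short	2	FALSE
OsPIN5c	357	7	Short	2	FALSE
OsPIN8	311	5	Short	2	FALSE
OsPIN9	426	10	Reduced	3	FALSE
PpPIN1A	713	9	Long	1	FALSE
PpPIN1B	713	9	Long	1	FALSE
PpPIN1C	698	9	Long	1	FALSE
PaPIN1	699	10	Long	1	FALSE
PaPIN2	426	3	C-terminal TMD only	4	FALSE
PaPIN3	625	8	Long	1	FALSE
PtoPIN1	619	7	Long	1	FALSE
PttPIN1	614	9	Long	1	FALSE
PttPIN2	640	9	Long	1	FALSE
PttPIN3	588	9	Long	1	FALSE
PtrPIN1	614	9	Long	1	FALSE
PtrPIN2	588	8	Long	1	FALSE
PtrPIN3	645	9	Long	1	FALSE
PtrPIN4	534	9	Long	1	FALSE
PtrPIN5	532	8	Long	1	FALSE
PtrPIN6	649	9	Long	1	FALSE
PtrPIN7	609	9	Long	1	FALSE
PtrPIN8	587	9	Long	1	FALSE
PtrPIN9	633	9	Long	1	FALSE
PtrPIN10	547	10	Long	1	FALSE
PtrPIN11	346	9	Short	2	FALSE
PtrPIN12	346	10	Short	2	FALSE
PtrPIN13	355	8	Short	2	FALSE
PtrPIN14	358	8	Short	2	FALSE
PtrPIN15	370	8	Short	2	FALSE
PtrPIN16	304	6	Short	2	FALSE
Ppe002528	662	10	Long	1	FALSE
Ppe002944	619	9	Long	1	FALSE
Ppe003159	597	8	Long	1	FALSE
Ppe007621	361	9	Short	2	FALSE
Ppe021573	357	7	Short	2	FALSE
Ppe022797	550	9	Long	1	FALSE
Ppe024134	649	9	Long	1	FALSE
Ppe025174	602	8	Long	1	FALSE
Rc27985	544	8	Long	1	FALSE
Rc29662	635	8	Long	1	FALSE
Rc29816	646	10	Long	1	FALSE
Rc29822	313	7	Short	2	FALSE
Rc30128	357	9	Short	2	FALSE
Rc30180	613	8	Long	1	FALSE
SmPIN1-1	625	9	Long	1	FALSE
SmPIN1-2	617	9	Long	1	FALSE
SmPIN2-1	602	9	Long	1	FALSE
SmPIN2-2	716	9	Long	1	FALSE
SmPIN3-1	669	9	Long	1	FALSE
SmPIN3-2	672	9	Long	1	FALSE
SmPIN4-1	687	9	Long	1	FALSE
SmPIN5-1	636	9	Long	1	FALSE
SmPIN5-2	625	9	Long	1	FALSE
SbPIN1	371	9	Short	2	FALSE
SbPIN2	653	8	Long	1	FALSE
SbPIN3	362	7	Short	2	FALSE
SbPIN4	444	10	Reduced	3	FALSE
SbPIN5	336	7	Short	2	FALSE
SbPIN6	605	10	Long	1	FALSE
SbPIN7	583	9	Long	1	FALSE
SbPIN8	402	9	Short	2	FALSE
SbPIN9	600	10	Long	1	FALSE
SbPIN10	606	9	Long	1	FALSE
SbPIN11	626	9	Long	1	FALSE
VvPIN1a	604	8	Long	1	FALSE
VvPIN1b	591	8	Long	1	FALSE
VvPIN2	630	10	Long	1	FALSE
VvPIN5b	361	9	Short	2	FALSE
VvPIN5a	356	9	Short	2	FALSE
VvPIN6	532	9	Reduced	3	FALSE
VvPIN8	357	8	Short	2	FALSE
VvPIN9	463	8	Reduced	3	FALSE
ZmPIN1a	601	9	Long	1	FALSE
ZmPIN1b	595	8	Long	1	FALSE
ZmPIN1c	597	8	Long	1	FALSE
ZmPIN1d	580	8	Long	1	FALSE
ZmPIN2	626	9	Long	1	FALSE
ZmPIN5a	382	9	Short	2	FALSE
ZmPIN5b	385	7	Short	2	FALSE
ZmPIN5c	365	7	Short	2	FALSE
ZmPIN8	359	7	Short	2	FALSE
ZmPIN9	433	10	Short	2	FALSE
ZmPIN10a	610	8	Long	1	FALSE
ZmPIN10b	581	8	Long	1	FALSE
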