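Majority protein IDs	Gene names	Unique peptides	Reverse	Potential contaminant	Only identified by site	LFQ intensity mock_r1	LFQ intensity mock_r2	LFQ intensity mock_r3	LFQ intensity mock_r4	LFQ intensity treat_r1	LFQ intensity treat_r2	LFQ intensity treat_r3	LFQ intensity treat_r4	Intensity mock_r1	Intensity mock_r2	Intensity mock_r3	Intensity mock_r4	Intensity treat_r1	Intensity treat_r2	Intensity treat_r3	Intensity treat_r4
REV__AT1G00010.1	REV001	2	+			131045367	109827588	106820092	80422427	133444549	99383461	112419448	99061469	131045367	109827588	106820092	80422427	133444549	99383461	112419448	99061469
REV__AT1G00020.1	REV002	3	+			173621538	124954556	91687733	105914227	97745360	110371992	97406443	78159268	173621538	124954556	91687733	105914227	97745360	110371992	97406443	78159268
CON__P00761	TRYP_PIG	5		+		8470640	14022388	15690804	12872180	12944198	10221241	11307029	14412812	8470640	14022388	15690804	12872180	12944198	10221241	11307029	14412812
AT1G00040.1	SITE001	4			+	70377040	65707751	85244766	61164072	99595089	67154139	94192250	70452346	70377040	65707751	85244766	61164072	99595089	67154139	94192250	70452346
AT2G29970.1;AT2G29970.2	SMXL7	24				260019462	301445889	210754592	339277798	106994070	92943124	77634715	103754721	260019462	301445889	210754592	339277798	106994070	92943124	77634715	103754721
AT1G00060.1	PREY001	6				28934048	17738456	26850488	28605291	21195313	23412564	20178920	19595296	28934048	17738456	26850488	28605291	21195313	23412564	20178920	19595296
AT1G00070.1	PREY002	7				50776784	45760639	62041413	63198860	42572544	48421569	52570339	53781735	50776784	45760639	62041413	63198860	42572544	48421569	52570339	53781735
AT1G00080.1	PREY003	8				3849918	5604137	6815003	7366068	4938251	11731631	8587356	5663444	3849918	5604137	6815003	7366068	4938251	11731631	8587356	5663444
AT1G00090.1	PREY004	9				24611366	24746123	21939608	34004647	41567603	30797856	37077550	36589180	24611366	24746123	21939608	34004647	41567603	30797856	37077550	36589180
AT1G00100.1	PREY005	10				63548640	48657562	51240770	38420945	55319517	49691673	47769389	63121427	63548640	48657562	51240770	38420945	55319517	49691673	47769389	63121427
AT1G00110.1	PREY006	11				19228159	21391117	18987393	28069908	26308005	15022498	20130458	19759610	19228159	21391117	18987393	28069908	26308005	15022498	20130458	19759610
AT1G00120.1	PREY007	12				35007695	47035414	52693820	53496371	63006031	37345486	42156669	40573278	35007695	47035414	52693820	53496371	63006031	37345486	42156669	40573278
AT1G00130.1	PREY008	13				103265709	125299916	120788541	109010609	86872646	109835711	97571470	110718672	103265709	125299916	120788541	109010609	86872646	109835711	97571470	110718672
AT1G00140.1	PREY009	14				13086233	8739581	13599640	9912896	14929771	8262531	10103212	9426708	13086233	8739581	13599640	9912896	14929771	8262531	10103212	9426708
AT1G00150.1	PREY010	15				30876848	15664331	17897770	16241319	72497712	83248292	76412400	94150680	30876848	15664331	17897770	16241319	72497712	83248292	76412400	94150680
AT1G00160.1	MOCKONLY	5				99689061	119291666	142940094	123820220	0	0	0	0	99689061	119291666	142940094	123820220	0	0	0	0
AT1G00170.1	SPARSE1	4				117978712	105138381	0	0	113999747	109551247	112615822	0	117978712	105138381	0	0	113999747	109551247	112615822	0
AT1G00180.1	ALLMISS	3				0	0	0	0	0	0	0	0	0	0	0	0	0	0	0	0
AT1G00190.1	TREATSIDE	6				0	0	26348253	26417476	22625453	16865375	25149810	22144649	0	0	26348253	26417476	22625453	16865375	25149810	22144649
AT1G00200.1	SPARSE2	2				0	0	33973987	34694308	0	0	23477138	35230788	0	0	33973987	34694308	0	0	23477138	35230788
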