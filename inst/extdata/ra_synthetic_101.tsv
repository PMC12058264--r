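variant_id	chrom	pos	risk_allele	other_allele	odds_ratio	eaf
rs93133038	5	52412300	A	C	0.968489942722542	0.175282844691537
rs90780341	14	22179036	C	A	1.20359855942783	0.132517927745357
rs97593636	20	76668428	C	T	1.19380599503614	0.883262903476134
rs94669054	19	79477227	G	T	1.01644488253391	0.9484779025428
rs93998013	22	45292696	A	C	1.03696741857938	0.940423423540778
rs98061497	6	79172617	T	C	1.07244695364258	0.0782472636783496
rs93629884	17	55914978	G	T	0.929505977770819	0.1096985894721
rs90516968	16	55117445	T	C	0.963206221681561	0.308645131788217
rs90907780	8	64663713	G	A	1.12431616447584	0.280818343977444
rs99421414	15	13916795	G	T	1.05967795025176	0.893095713248476
rs98779672	17	2519108	G	A	1.04011202977409	0.679011029889807
rs97599747	1	14188950	G	T	1.02054819486056	0.840165272960439
rs95525451	20	13379189	A	C	0.851834273470269	0.264275360968895
rs90066078	16	11748668	T	G	1.07182059407813	0.286544852470979
rs98749662	21	39943455	G	T	0.943973860541207	0.243288407521322
rs90842033	1	94851914	C	T	1.05716145647302	0.0808468394912779
rs95918462	18	51984561	A	C	0.932260772620353	0.575899942661636
rs94883476	15	85996583	T	G	0.896155331341927	0.266895732702687
rs91766649	4	85244651	G	T	0.902436773739853	0.425965813454241
rs92091835	8	3657261	G	A	0.782174159146515	0.370897403848357
rs91114057	17	4566637	G	T	1.17947450260143	0.216295593930408
rs94288720	1	58767235	A	G	0.948781399687786	0.855135942529887
rs92959944	9	29303596	A	C	1.01740682042595	0.0995065340539441
rs97691240	18	98761739	A	C	0.869665316510325	0.419341162242927
rs97244610	5	63179976	G	A	1.10378731076584	0.701398132904433
rs96133047	20	7919991	A	G	0.828743198657771	0.550271873059683
rs99675346	14	63446908	T	G	0.990565101446851	0.144249507645145
rs94773155	20	22819362	A	C	1.08260010424247	0.383745088637806
rs90337603	6	68460311	G	A	0.940783316114284	0.768631716584787
rs91710072	19	98813359	C	A	0.963070214724025	0.201410795073025
rs97771441	19	31959300	G	T	0.978644437148787	0.656489514675923
rs93456010	1	15360945	T	C	0.958857852146392	0.593182047340088
rs98651325	10	94471300	C	T	0.923779612067384	0.259129169979133
rs90608031	12	37901189	T	C	1.00203147045462	0.170475334348157
rs92348498	4	49839837	A	G	1.00676060128244	0.454781955014914
rs98892608	7	65486182	T	G	0.874866632715281	0.269501140434295
rs93810674	6	56293650	T	C	1.03930665196428	0.321853941865265
rs90675372	17	4843876	T	C	0.997895378653033	0.782967250165529
rs98017081	10	65110314	G	T	1.11017826195911	0.436241876496933
rs95698133	18	30334621	G	A	1.02924301752796	0.811256227223203
rs99719170	18	45132288	A	C	0.934204796383109	0.866327173192985
rs99032228	13	27474116	G	T	1.23909570438271	0.119248995953239
rs99607988	15	96331050	T	G	1.04377934378889	0.552223961940035
rs91231582	11	78245101	G	T	0.867247314882057	0.482237123814411
rs90712406	18	52946090	C	T	0.984631416927079	0.664592419494875
rs97026477	2	35737944	G	A	1.24708667334614	0.16819321368821
rs97385632	4	64749045	A	C	1.0202055600599	0.827219031867571
rs96073878	11	50554238	T	G	0.832979512030748	0.924685970973223
rs94719280	2	11540597	C	T	0.959269362859947	0.585553767578676
rs95156071	7	22296936	C	A	0.965359883555212	0.795565559295937
rs92963867	7	17796386	C	T	1.05504010632726	0.629483132250607
rs90486930	7	96796664	T	G	0.903390704851383	0.319572625868022
rs99615081	1	65530204	A	G	0.951488694086868	0.672210840671323
rs90030275	12	89332339	G	A	1.03849632061757	0.436357981571928
rs94725942	7	69558647	G	T	1.07124454990895	0.680802880460396
rs99612981	4	3276563	A	C	1.0412867198814	0.887789553846233
rs95910934	10	52214289	G	A	1.08700043656269	0.33461798322387
rs95336788	21	72431613	A	G	1.04916486411744	0.241785546531901
rs97186990	17	81024257	T	G	1.14523119397616	0.390555699705146
rs91676963	14	33658180	A	G	0.919747476121651	0.426498145400546
rs93069693	17	19420176	T	G	0.928057556256778	0.869035217119381
rs97225123	6	49090235	C	A	0.917449337407966	0.162574617797509
rs92646301	5	12633988	G	T	1.04590498671955	0.779547038045712
rs98850909	15	61319973	C	T	1.30465368430776	0.945584715367295
rs90780935	7	85706248	G	T	0.922053097282121	0.731848017196171
rs93380864	6	36661400	T	C	0.950697468716645	0.872198846191168
rs97737365	6	97553301	G	A	1.10756519328172	0.487894204794429
rs96038095	15	56463453	C	A	0.963202009254405	0.853165096207522
rs99017091	9	5269712	G	T	0.954402262379201	0.158747754292563
rs90492300	4	97202920	C	A	1.07872126034602	0.138851362303831
rs94814354	16	79995791	T	G	0.889082327266367	0.180720182764344
rs98270352	2	11634551	T	G	0.801234180070001	0.710676966141909
rs94412292	21	79466945	G	T	1.08987001632523	0.223515131440945
rs94893277	10	32746681	G	A	1.00723739415454	0.936082094325684
rs98591935	22	11387314	A	G	1.15238219722308	0.944583255215548
rs93571831	11	23438117	G	A	1.2382519515509	0.624249690677971
rs98676248	9	86283786	A	G	1.01466474470251	0.599361478257924
rs97311469	14	59560076	C	A	1.06270042296722	0.347455180785619
rs94982839	8	25754860	A	G	0.927889815897244	0.570646900427528
rs98275001	4	14280711	T	G	1.03297097668351	0.749190650531091
rs99353358	18	46970363	G	A	1.17119944024094	0.429006759123877
rs93278122	7	39406726	G	A	1.10971604392821	0.462229644367471
rs95889909	8	40098304	G	T	0.930593959492883	0.648227441497147
rs93991079	18	12221737	C	A	1.18029714092483	0.705701601481996
rs98483850	14	97830937	G	A	0.938629588037073	0.144206363055855
rs97211212	3	5434811	G	T	1.04476991154934	0.276989641692489
rs97526998	4	23429578	A	C	0.952776666524209	0.203389091859572
rs99289620	7	89848454	C	T	0.943669682185079	0.845313266268931
rs93679270	5	28328317	G	T	1.07879163522945	0.374199870973825
rs94248418	11	94495230	C	T	1.04423754719269	0.213673633825965
rs91429417	4	84255326	C	T	0.918800236547709	0.794821187620983
rs95407769	8	9929058	G	A	0.983611869097246	0.292084966716357
rs94029851	5	41524555	C	A	1.04384210291675	0.239392922422849
rs94356958	11	71645694	G	A	0.957919045291453	0.343640307174064
rs94466376	11	16847835	G	T	1.18627608607991	0.232653629826382
rs91224840	17	50458164	G	T	1.23998355262031	0.868096896377392
rs98954751	17	5036252	T	G	0.978999919681316	0.796038468577899
rs97648955	10	15503787	G	A	1.00678965646556	0.862408162397332
rs97708186	14	7416954	A	G	0.975346306096913	0.648468797770329
rs99316286	17	69640411	A	C	1.02475334033411	0.828325680503622
rs90136120	3	37674839	G	A	0.872029914143485	0.691711868345737
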