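event_id	gene_id	type	inclusion_isoforms	total_isoforms	CTRL1_c1	CTRL1_c2	CTRL1_c3	CTRL1_c4	CTRL1_c5	CTRL1_c6	CTRL1_c7	CTRL1_c8	CTRL1_c9	CTRL1_c10	CTRL1_c11	CTRL1_c12	CTRL1_c13	CTRL1_c14	CTRL1_c15	CTRL1_c16	CTRL1_c17	CTRL1_c18	CTRL1_c19	CTRL1_c20	HSCR1_c1	HSCR1_c2	HSCR1_c3	HSCR1_c4	HSCR1_c5	HSCR1_c6	HSCR1_c7	HSCR1_c8	HSCR1_c9	HSCR1_c10	HSCR1_c11	HSCR1_c12	HSCR1_c13	HSCR1_c14	HSCR1_c15	HSCR1_c16	HSCR1_c17	HSCR1_c18	HSCR1_c19	HSCR1_c20	HSCR2_c1	HSCR2_c2	HSCR2_c3	HSCR2_c4	HSCR2_c5	HSCR2_c6	HSCR2_c7	HSCR2_c8	HSCR2_c9	HSCR2_c10	HSCR2_c11	HSCR2_c12	HSCR2_c13	HSCR2_c14	HSCR2_c15	HSCR2_c16	HSCR2_c17	HSCR2_c18	HSCR2_c19	HSCR2_c20
E001	G0005	SE	E001.i1	E001.i1,E001.i2	0.32808120012315317	0.36731553116166782	0.40234866474446268	0.2398875472333416	0.22941972220770246	0.23936173215810064	0.38325427623147085	0.36146692934046709	0.32973538705689415	0.37595800784531447	0.35989404122880297	0.31032545447176058	0.52013489831369353	0.27103563974379663	0.2979774891792436	0.26368041778339824	0.39726579353856178	0.27483406275885869	NA	0.27449276977393422	0.20012036932695751	0.22904374210576053	0.21730449463121795	0.23913646206513181	0.19724758810588996	0.29811751593652724	0.3142857153865799	0.27971126981892919	0.39585099905368476	0.33830488827707039	0.23933102145718935	0.41765459556170981	0.1890472959475393	0.4055303217262608	0.45694405054450404	0.23585014520333375	0.41678976055827044	0.39560658811025567	0.31540387623319877	NA	0.71440851403186156	0.70275764738754576	0.71838865455863887	0.70955079427992962	0.65219015290573135	0.50565671327081929	0.63643844969697128	0.65574181805644005	0.73935848127419179	0.58891218064159545	0.76444619111899359	0.66723978311354559	0.72287640363695715	0.684630967951667	0.67393837901771048	0.61637945365436397	0.64514181429132922	0.6918680561910735	0.68517165363170296	0.61419722338929628
E002	G0002	SE	E002.i1	E002.i1,E002.i2	0.24483765361642884	0.25750110739034909	0.32717041229240812	0.2277007132600751	0.19372201450962165	0.21752612515979713	0.38709581849671115	0.38657318496025295	0.27641815707823608	0.34828350610247255	0.22304854365828242	0.22301817051968392	0.37031608968524027	0.1907761567180547	0.13689753810378499	0.19741221609683077	0.26134934555452322	0.24680195679862516	0.23103462048818518	0.24420364657840166	0.14311861489678521	0.15537932550011294	0.219687200242311	0.16081773755834444	0.22439643446083357	0.2185889361259809	0.13247679638815288	0.22825592532817196	0.27305160621163321	0.23004957539120055	0.23088700270531845	0.45961552525951316	0.12019921151640829	0.31583398314879985	0.31127792343058303	0.34893682476320564	0.33101314640683693	0.42460088877404223	0.23840439874889727	NA	0.65367423711560235	0.72286636004348548	0.67586124222661448	0.63919749590507258	0.46995383504788407	0.48188090873443806	0.50972040231736127	0.4900951417726962	NA	0.56725193717161537	0.66912179761787716	0.57050252980160987	0.57525533606761314	0.57550290747454336	0.55981356576851915	0.45040200815337716	0.55124865684366775	0.60128045894263082	0.50589190174975995	0.52694114258263014
E003	G0003	SE	E003.i1	E003.i1,E003.i2	0.62179816460497439	0.51077779065760986	NA	0.74634412666358585	0.63475212448810892	0.53172859547814655	0.57013487657197659	0.52784996633592585	0.72540477894831612	0.38923103268762832	0.54450329388687191	0.57650185032607459	0.25854873549967572	0.65918676518899078	0.56252922029088781	0.72076392268769096	0.5148311926023067	0.58143057860045866	0.52818004405744035	0.54467390781882763	0.64556690733259336	0.66095256894957533	0.63560499348863486	0.66456609564540192	0.72790346767855285	0.60920239020736544	0.5614548861997688	0.59323710650297934	0.5131730562848642	0.64847621017449986	0.6996731320919688	0.40259531435605628	0.59242836037540003	0.51070987454022432	0.50915754423210102	0.7335655108877055	0.48691152252119591	0.55890931170146296	0.62981492434311603	0.57428056610939571	0.17218864208987253	0.18386486918715034	0.17363297560683405	0.18174247059964027	0.27577600261171303	0.36837317975152423	0.16148543657213546	0.25838929275602618	0.10593850772219955	0.29385615238574359	NA	0.29207333456949169	0.12109993781662831	0.25386683379079672	0.28140743799546197	0.28270224743851491	0.1337539508589019	0.18760191114194558	0.18553778532457366	0.29920477959107195
E004	G0004	MX	E004.i1	E004.i1,E004.i2	0.32808120012315317	NA	0.40234866474446268	0.2398875472333416	0.22941972220770246	0.23936173215810064	0.38325427623147085	0.36146692934046709	0.32973538705689415	0.37595800784531447	0.35989404122880297	0.31032545447176058	0.52013489831369353	0.27103563974379663	0.2979774891792436	0.26368041778339824	0.39726579353856178	0.27483406275885869	0.2659677869131033	0.27449276977393422	0.20012036932695751	0.22904374210576053	0.21730449463121795	0.23913646206513181	0.19724758810588996	0.29811751593652724	0.3142857153865799	0.27971126981892919	0.39585099905368476	0.33830488827707039	0.23933102145718935	0.41765459556170981	0.1890472959475393	NA	0.45694405054450404	0.23585014520333375	0.41678976055827044	0.39560658811025567	0.31540387623319877	0.31184802117455879	0.71440851403186156	0.70275764738754576	0.71838865455863887	0.70955079427992962	0.65219015290573135	0.50565671327081929	0.63643844969697128	0.65574181805644005	0.73935848127419179	0.58891218064159545	0.76444619111899359	0.66723978311354559	0.72287640363695715	0.684630967951667	0.67393837901771048	0.61637945365436397	0.64514181429132922	NA	0.68517165363170296	0.61419722338929628
E005	G0005	MX	E005.i1	E005.i1,E005.i2	0.67191879987684677	NA	0.59765133525553726	0.7601124527666584	0.77058027779229754	0.76063826784189936	0.61674572376852921	0.63853307065953291	0.6702646129431058	0.62404199215468559	0.64010595877119703	0.68967454552823937	0.47986510168630647	0.72896436025620337	0.7020225108207564	0.73631958221660176	0.60273420646143827	0.72516593724114131	0.7340322130868967	0.72550723022606578	0.79987963067304246	0.77095625789423949	0.78269550536878207	0.76086353793486816	0.80275241189411006	0.70188248406347276	0.6857142846134201	0.72028873018107076	0.6041490009463153	0.66169511172292961	0.76066897854281068	0.58234540443829019	0.81095270405246067	NA	0.54305594945549596	0.76414985479666631	0.58321023944172956	0.60439341188974427	0.68459612376680123	0.68815197882544121	0.28559148596813844	0.29724235261245424	0.28161134544136113	0.29044920572007038	0.34780984709426865	0.49434328672918071	0.36356155030302872	0.34425818194355995	0.26064151872580821	0.41108781935840455	0.23555380888100641	0.33276021688645441	0.27712359636304285	0.315369032048333	0.32606162098228952	0.38362054634563603	0.35485818570867078	NA	0.31482834636829704	0.38580277661070372
E006	G0006	SE	E006.i1	E006.i1,E006.i2	0.25810671940301105	0.31911494385748351	0.30005915576606512	0.18948718092646558	0.25635041576774953	0.3218705798145976	0.26225432405617183	0.20370053660083304	0.3294023259807794	0.21618540964424196	0.25247323256266307	0.3356650506082734	0.20018016147936918	0.17760500233768328	0.28511376475248257	0.29231225563486957	0.24198258698963127	0.30930990224168925	0.32287206593377205	0.3016103752735666	0.3359907985575899	0.32112420062665981	0.24771841757467333	0.22593966177920102	0.22821692208580069	0.30182681192825089	0.26539504950571868	0.27103622060817245	0.33745653663739567	0.30776095523508318	0.21447315500794853	0.17194802050082059	0.27414490597164626	0.21622997153094603	0.21732562496197233	0.11298476225697573	0.1423307159109066	0.14214621193613813	0.32120924798874328	0.26595207189886039	0.37913924957951189	0.26844599371135386	0.19980420472729865	0.24428578128949702	0.14165924459202461	0.23607444471899444	0.16735228384587797	NA	0.225061759341569	0.23574201488192892	0.23187955980311825	0.23662000749612769	0.14083109019707798	0.238268360610284	0.22755852354228492	0.20607254257291505	0.2638711862169808	0.27051496453511892	0.27269520998973357	0.21793640360296496
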