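variant	beta_X1	se_X1	beta_X2	se_X2	beta_X3	se_X3	beta_outcome	se_outcome
v1	0.396422329280892	0.0228081284310406	0.0398039880438578	0.0229162642660817	-0.0429558796919442	0.0239576430119894	0.13756965127277	0.0340002533946143
v2	0.371485966573736	0.0228880634615081	0.0178744921187197	0.0228998619898685	0.100888127891151	0.0238896868281536	0.0692428812284961	0.0343268112245342
v3	0.372522169105487	0.0229577183011823	0.0831309840210344	0.0229332877164494	0.232159180043122	0.0237330626511585	0.0168626986423246	0.033752776796596
v4	0.321146644108112	0.0235727081454418	0.116129318555641	0.0232980018885804	0.222482037607499	0.0241782069863542	-0.0366212827118793	0.0337056614754235
v5	0.320161830031286	0.0235839953408757	0.11014954175114	0.0233128056810512	0.26868865060688	0.0240685124684194	-0.0722300398280139	0.0342615246979971
v6	0.056922899623447	0.0236461229010217	-0.022748307657154	0.0229309259991252	0.0912555908237626	0.023933037861114	0.0191960731636797	0.0338634878827755
v7	0.150084213482206	0.0235295850740609	0.108759722826447	0.0228553056607393	-0.140049202283919	0.0238594906972428	0.0746731295876296	0.0342818084666116
v8	-0.105042873950274	0.0236302223820502	0.144563790210068	0.0228441351761163	0.133472131707099	0.0239091390982824	-0.0930055371019835	0.033865052107492
v9	0.115126332253354	0.0234406025404948	0.0880957721909305	0.0227437568544165	0.256475466892254	0.0234745898697379	-0.076680085459547	0.0340127248630847
v10	0.179055251824895	0.0239481162898353	0.199525170890373	0.0231575252062173	0.161779396993709	0.0242998746762086	-0.102960661950329	0.0328928143151461
v11	0.0649274891527573	0.023855300957578	0.0513667085960182	0.0231270198591041	0.278103678348653	0.0237903276754896	-0.185725871872213	0.0346610553711093
v12	0.274280312563224	0.0232148765152101	0.0554287291524801	0.0228718114834647	0.4168950016943	0.0230030472416646	-0.111383157592063	0.0341549805663664
v13	0.211969969723441	0.0231807236121487	0.0847099145870177	0.0226602450379066	0.427940170190878	0.0227464069913639	-0.133999235857733	0.0341086112368168
v14	-0.0307785672155	0.0242318713546897	0.187809341132472	0.0233010210044916	0.230355659772951	0.0242858759269216	-0.159561444374769	0.0333067365499172
v15	0.246332338615813	0.0236796743045806	0.14291232735049	0.0231481009242376	0.395176160504082	0.023498782227963	-0.139564105120452	0.0336539488348764
v16	0.107468942955253	0.0238588712280792	0.132878853338338	0.0230864824481807	0.298252215633315	0.0237725315352842	-0.150871524158952	0.0343981529760018
v17	0.260416366630889	0.0236195513487901	0.148899321644849	0.0231171633911674	0.0492852554485026	0.0242808352053135	0.0446117594550484	0.034309407827099
v18	0.152056974709573	0.0239104068909263	-0.0134195049428272	0.0232892267311715	0.213252216690929	0.0241144587451672	-0.0761606584969485	0.0347977473514639
v19	0.257542127045136	0.0228819200813309	-0.00479793613256701	0.0225249774326165	-0.233528949226342	0.0232578662664074	0.202054413054856	0.0342054126516391
v20	0.155064987741034	0.024150297722691	0.215345946670862	0.0232783228385231	0.363900260985414	0.0239130373191504	-0.159925980240735	0.0340373052322871
v21	0.280504465206124	0.02319296656956	0.198913276370569	0.0226682125089918	0.176555630297238	0.0237625384278077	-0.0230301617184996	0.033863777740971
v22	0.15806457341385	0.0238973512136947	0.204629108813276	0.0230610291037653	0.290357224596442	0.0239088307619586	-0.16093492960408	0.0333791081434857
v23	0.262030264492543	0.0234313490586546	0.0836266679100448	0.0230234687258181	0.292187261132424	0.0236630075096856	-0.0896245244428743	0.0339967927317708
v24	0.163592544142644	0.0235007358214087	0.10986225782695	0.0228478836328276	0.0029454492785537	0.0239556707800199	0.0596716945201944	0.0344312036548241
v25	0.275964769405229	0.0239978344854256	0.0755727575134051	0.0236092983552031	0.300241990499042	0.0242539371883413	-0.0861024516748037	0.0346592266372291
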