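gene_name	location	gene_model	comments
BdWRKY1	Bd2:14220256.14222873	Bradi2g16150.1	Group IIb
BdWRKY2	Bd2:3983627.3984262	Bradi2g05510.1	Group IIc
BdWRKY3	Bd2:58924622.58926999	Bradi2g62130.1	Group IIc. Gene model incorrect.
BdWRKY4	Bd2:9403194.9408009	Bradi2g11170.1	Group IIb
BdWRKY5	Bd2:6965062.6969356	Bradi2g08620.1	Group IIb
BdWRKY6	Bd3:17079694.17080883	Bradi3g18580.1	Group IId
BdWRKY7	Bd4:1276705.1278741	Bradi4g01950.1	Group I
BdWRKY8	Bd2:52655598.52657803	Bradi2g53510.1	Group III
BdWRKY9	Bd2:52646076.52649410	Bradi2g53500.1	Group III
BdWRKY10	Bd4:47804750.47805919	Bradi4g44370.1	Group III
BdWRKY11	Bd2:30385271.30389483	Bradi2g30790.1	Group III
BdWRKY12	Bd3:57392174.57394564	Bradi3g57710.1	Group IIb
BdWRKY13	Bd3:36924901.36926175	Bradi3g34570.1	Group IIe, Gene Model incorrect.
BdWRKY14	Bd4:36119270.36124180	Bradi4g30370.1	Group IIa. Prediction using 40kb sequence for Bradi4g30360 and Bradi4g30370 together.
BdWRKY15	Bd4:47786980.47788750	Bradi4g44350.1	Group III
BdWRKY16	Bd2:46341174.46344106	Bradi2g45900.1	Group IIc
BdWRKY17	Bd2:30398035.30400975	Bradi2g30800.1	Group III
BdWRKY18	Bd1:1580683.1586394	Bradi1g02340.1	Group I. Second domain is truncated. Possible pseudogene.
BdWRKY19	Bd4:33637416.33639506	Bradi4g28280.1	Group III
BdWRKY20	Bd1:62421625.62422845	Bradi1g63220.1	Group III
BdWRKY21	Bd3:8007304.8009052	Bradi3g09810.1	Group IIe
BdWRKY22	Bd1:47430434.47433797	Bradi1g48770.1	Group III
BdWRKY23	Bd1:5717967.5719246	Bradi1g08100.1	Group IIc. Gene model incorrect.
BdWRKY24	Bd2:49173622.49177995	Bradi2g49020.1	Group IIc
BdWRKY25	Bd2: 52664751 - 52666466	Bradi2g53520.1	Group III
BdWRKY26	Bd4:21655844.21659743	Bradi4g19060.1	Group IIc
BdWRKY27	Bd1:5619653.5623406	Bradi1g07970.1	Group I
BdWRKY28	Bd1:14207355.14209349	Bradi1g17660.1	Group III
BdWRKY29	Bd4:47797837.47799556	Bradi4g44360.1	Group III
BdWRKY30	Bd2:13707176.13708809	Bradi2g15360.1	Group IIc
BdWRKY31	Bd1:11188915.11191904	Bradi1g14300.1	Group IId
BdWRKY32	Bd5:16639846.16643118	Bradi5g13090.1	Group I
BdWRKY33	Bd5:20666685.20686684	-	Group IIc. No Gene Model
BdWRKY34	Bd5:6201425.6206424	Bradi5g04820.1	Group IId Gene Model Incorrect.
BdWRKY35	Bd5:23482100.23483388	Bradi5g20700.1	Group II d
BdWRKY36	Bd5:23193818.23196993	Bradi5g20290.1	Group IIe
BdWRKY37	Bd3:41662537.41665191	Bradi3g39340.1	Group I
BdWRKY38	Bd3:18514515.18520937	Bradi3g19640.1	Group I
BdWRKY39	Bd3:4354442.4356174	Bradi3g06070.1	Group IIa
BdWRKY40	Bd3:37214494.37216071	Bradi3g34850.1	Group III
BdWRKY41	Bd3:51584113.51587575	Bradi3g50360.1	Group IIc
BdWRKY42	Bd3:53316886.53321459	Bradi3g52420.1	Group IIe
BdWRKY43	Bd4:31071952.31076951	Bradi4g25720.1	Group III, Gene Model Incorrect.
BdWRKY44	Bd2:19779563.19782548	Bradi2g22230.1	Group III
BdWRKY45	Bd2:52860060.52862718	Bradi2g53760.1	Group I
BdWRKY46	Bd2:19960366.19962573	Bradi2g22440.1	Group I
BdWRKY47	Bd2:37371.39452	Bradi2g00280.1	Group I
BdWRKY48	Bd2:3979821.3981719	Bradi2g05500.1	Group IIb
BdWRKY49	Bd2:3815724.3825723	-	Group IIc. No Gene Model
BdWRKY50	Bd2:33674703.33675549	Bradi2g33540.1	Group IIc
BdWRKY51	Bd2:14038105.14040104	Bradi2g15880.1	Group III. Gene Model short.
BdWRKY52	Bd2:42525077.42527076	-	Group IIc. No gene Model.
BdWRKY53	Bd2:44578672.44580858	Bradi2g44090.1	Group IIc
BdWRKY54	Bd2:16801079.16803652	Bradi2g19070.1	Group IIc
BdWRKY55	Bd2:45857664.45858974	Bradi2g45480.1	Group III
BdWRKY56	Bd2:16474142.16475652	Bradi2g18530.1	Group IIc
BdWRKY57	Bd2:53553539.53556063	Bradi2g54720.1	Group IIc, Gene Model Incorrect.
BdWRKY58	Bd2:48426948.48428121	Bradi2g48090.1	Group IIc
BdWRKY59	Bd4:48418469.4842114	Bradi4g45290.1	Group I. Gene Model Short.
BdWRKY60	Bd4:39074575.39078767	Bradi4g33370.1	Group IIc
BdWRKY61	Bd4:5576052.5581378	Bradi4g06690.1	Group I
BdWRKY62	Bd4:9350003.9357060	Bradi4g09890.1	Group I
BdWRKY63	Bd4:1992609.1995531	Bradi4g02680.1	Group IId
BdWRKY64	Bd1:18715369.18721632	Bradi1g23340.1	Group I
BdWRKY65	Bd1:46394072.46396455	Bradi1g47690.1	One and a half WRKY domains followed by a FAR1-s domain and a MULE transposon.
BdWRKY66	Bd1:13042696.13049431	Bradi1g16120.1	Group I
BdWRKY67	Bd1:18197079.18200281	Bradi1g22680.1	Group I
BdWRKY68	Bd1:26329079.26330580	Bradi1g30870.1	Group IIa
BdWRKY69	Bd1:36017779.36022778	-	Group IIe. No Gene Model
BdWRKY70	Bd1:49453669.49457672	Bradi1g51030.1	Group IIb
BdWRKY71	Bd1:58314278.58317315	Bradi1g59180.1	Group IIc
BdWRKY72	Bd1:10018159.10019283	Bradi1g13210.1	Group IIc. WKKY group
BdWRKY73	Bd1:724757.729756	Bradi1g01060.1	Group IIe. No Gene Model.
BdWRKY74	Bd1:6545010.6548310	Bradi1g09170.1	Group IId
BdWRKY75	Bd1:70813782.70818781	-	Retrotransposon with N-terminal part of WRKY domain.
BdWRKY76	Bd2:14428190.14433051	Bradi2g16360.1	Group IIc. Gene Model Incorrect
BdWRKY77	Bd2:49902436.49907435	-	Group IIe. No Gene Model.
BdWRKY78	Bd1:63118295.63119746	Bradi1g63910.1	Group III
BdWRKY79	Bd2:44782012.44783510	Bradi2g44270.1	Group III
BdWRKY80	Bd2:49068600.49073599	Bradi2g48910.1	Group IIe
BdWRKY81	Bd2:13725107.13735106	-	Group IIe. No Gene model.
BdWRKY82	Bd2:44526356.44531355	-	Group IIe. No Gene Model.
BdWRKY83	Bd2:19783798.19788797	Bradi2g22240.1	Group III. Gene Model Incorrect.
BdWRKY84	Bd2:52617265.52627264	Bradi2g53480.1	Group III. Gene Model Incorrect
BdWRKY85	Bd2: 52628591 - 52629373	Bradi2g53490	Group III. Gene Model Incorrect.
BdWRKY86	Bd4:47782844.47784664	-	Group III.No Gene Model
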