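"taxon","age_min","age_max"
"fossil_01",225.327414906915,228.522920494299
"fossil_02",242.504525743628,249.889228880609
"fossil_03",235.350995177943,244.535974929649
"fossil_04",181.902033000346,185.625269814487
"fossil_05",153.596505158924,159.552500426181
"fossil_06",163.527014756566,165.764575459054
"fossil_07",129.869779913899,138.017462368336
"fossil_08",146.689292153357,150.285880601047
"fossil_09",198.776740089389,203.705810876894
"fossil_10",170.655263301324,174.662002342161
"fossil_11",198.673918244785,200.758974706179
"fossil_12",218.986664331823,228.235361886516
"fossil_13",197.067626234951,206.398981113793
"fossil_14",145.954492689867,154.495153572235
"fossil_15",150.22846661244,156.5022244129
"fossil_16",157.282240673954,159.962893061394
"fossil_17",140.491692489381,144.106836753334
"fossil_18",126.064612450147,135.258557781646
"fossil_19",108.584090742247,114.265325966256
"fossil_20",135.534661849239,143.683819831559
"fossil_21",99.2155583838696,107.834144026297
"fossil_22",90.1433645661281,99.8720198559867
"fossil_23",102.902495113961,109.54518349079
"fossil_24",92.6087435188064,96.4382493702987
"fossil_25",84.4993046927107,90.4999533030045
"fossil_26",67.9284749824877,72.4442553419943
"extant_01",0,0
"fossil_27",70.2488862125588,77.5643962657464
"fossil_28",76.3309413156768,79.7337228711059
"fossil_29",136.870078739419,145.913085606589
"fossil_30",144.202668117706,148.600746063863
"fossil_31",207.605668891098,216.661303516354
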