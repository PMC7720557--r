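((fossil_01[&age=226.0513239]:27.13516554,(fossil_02[&age=244.3034896]:1.851081436,fossil_03[&age=235.4817485]:10.67282259)[&age=246.1545711]:7.031918362)[&age=253.1864894]:26.81351058,(((fossil_04[&age=182.2358286]:2.17689788,(fossil_08[&age=150.15813]:22.04072437,(fossil_05[&age=157.1414683]:13.85035343,(fossil_06[&age=165.0618937]:4.704492587,fossil_07[&age=134.5668936]:35.19949273)[&age=169.7663863]:1.22543545)[&age=170.9918217]:1.207032606)[&age=172.1988543]:12.21387218)[&age=184.4127265]:53.79204176,(fossil_09[&age=200.1979608]:23.86511653,(fossil_10[&age=172.4051619]:28.09999603,fossil_11[&age=198.7414638]:1.763694178)[&age=200.5051579]:23.55791934)[&age=224.0630773]:14.14169099)[&age=238.2047683]:17.46528276,(fossil_12[&age=224.6603686]:11.07957741,(fossil_31[&age=214.2247416]:11.65049157,(fossil_13[&age=197.5503401]:3.818625799,((fossil_14[&age=153.6462996]:10.42762647,(fossil_15[&age=151.8549754]:7.872966058,fossil_16[&age=157.9602838]:1.767657657)[&age=159.7279415]:4.345984611)[&age=164.0739261]:20.50745498,(fossil_30[&age=147.3762975]:30.09224897,((fossil_17[&age=144.0470445]:2.214075944,(fossil_18[&age=127.9665778]:8.531495601,fossil_19[&age=110.3793404]:26.11873304)[&age=136.4980734]:9.76304702)[&age=146.2611204]:25.20335326,(fossil_20[&age=142.0257416]:12.95191191,(fossil_29[&age=140.8110474]:5.445393184,(((fossil_21[&age=107.1951302]:0.3675053017,fossil_22[&age=93.85108603]:13.71154948)[&age=107.5626355]:2.52965773,(fossil_23[&age=103.3376666]:4.11017511,fossil_24[&age=95.71604477]:11.73179697)[&age=107.4478417]:2.644451498)[&age=110.0922932]:31.56763449,(fossil_28[&age=77.94615611]:13.41553084,(fossil_25[&age=88.37541779]:0.4660294425,(fossil_27[&age=73.29907279]:2.98658982,(fossil_26[&age=70.24366949]:5.697721638,extant_01[&age=0]:75.94139113)[&age=75.94139113]:0.3442714802)[&age=76.28566261]:12.55578462)[&age=88.84144723]:2.520239716)[&age=91.36168694]:50.29824078)[&age=141.6599277]:4.596512899)[&age=146.2564406]:8.721212884)[&age=154.9776535]:16.48682019)[&age=171.4644737]:6.004072755)[&age=177.4685464]:7.112834634)[&age=184.5813811]:16.7875848)[&age=201.3689659]:24.50626732)[&age=225.8752332]:9.864712771)[&age=235.739946]:19.93010507)[&age=255.670051]:24.32994896)[&age=280];
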