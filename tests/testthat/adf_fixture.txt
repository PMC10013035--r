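0
1.1786726921402924
1.0177134807593313
0.22472791592423125
-0.14932965917752536
-2.8787752072729602
-1.4765014579186031
-1.4443789965237024
-0.46672385452303772
0.17055743108795002
1.6220362851232968
0.54000238291310421
0.71818537929991111
2.3013239690400495
0.71378365853757775
0.48566579666092752
0.37184239761089311
-1.2838229077674923
-0.33008816577583894
-1.5436675642357838
0.68704931524202673
-1.0939449547307096
-0.35474179062797667
-0.31909923034474025
0.24509640947563066
0.69895475438127497
-0.60550681037614695
0.12225277951186192
-0.62814424885489606
0.39026117432196894
-1.139637205880127
-1.5504794391796548
-0.9950445198384481
0.24420853404209308
-0.21236951328814185
-0.28302896304913017
1.413438893768173
1.6670568785416942
0.97998090553962147
-0.064435287002547081
-0.75505212190261606
-0.9739440435405573
-1.5223629345645515
-0.52757198272994377
0.32266306583834536
1.0709160466470031
-0.46976798517701279
-0.3816133683052087
-0.85593889813451485
1.7383622800162426
2.2824741304567908
-0.45723967265380971
1.027613352625607
1.6191650542071421
1.2491282337457148
1.8780165029801301
2.3122313790288791
1.3924939704714419
1.5467350103896838
0.45558401576717183
0.16501500181146159
0.1830776971088543
0.79387509105922649
0.41047569198017503
0.25636758150244299
0.58158070689206531
-1.2586317491503987
-0.41162327834565926
0.74377283675199557
1.530982073277001
1.6292445534851385
0.23862610453991384
0.81982194031841771
1.4960286698236802
1.4759940919572851
0.34328998418020729
0.67978466069448862
-0.21608808411125352
-1.1542181507712008
0.18114040521402031
0.73031732568943664
2.0566757058235523
2.7472805235977011
1.0741409600655962
0.28809090585645852
1.7898141412267092
0.029513659499959655
0.42799981586514668
-0.22623692090595993
-0.82624333830171026
-0.40549152920484449
0.92146667833889184
0.61612774023097583
0.26147577994923854
-0.70024890955821806
-0.86358225147467527
-0.52988279690155971
-0.45623963447052862
1.5791070773821516
0.53692173804104959
1.4783432940516408
-0.20450664592315027
-0.45752760053316915
-2.0315710220752234
-0.88440079246681746
-1.7747867319077109
0.041670289632944835
-0.8047267602084065
0.21293448926753278
1.0144385226482147
-0.17010105399161524
-1.3508396576502839
-1.461913655413507
-1.2861245925300075
-0.74338099908636579
0.80034191443830838
0.80834994628488599
-0.32587706529533694
-1.7798046371602481
-1.2756629526920042
-2.0107240730365006
-1.2821113171423029
-1.46755119133458
-1.836818981001918
-0.7086173809218963
0.14798862104349425
-0.67986056378629944
-1.6184171073442088
0.026211912999115961
0.019305130027344311
1.0304341677135604
-0.14416598866185515
-0.47450359505777279
0.32159323108792032
2.3436838324947455
1.7631936745078263
1.6172365708489951
-0.22239365917274123
0.082446488226385811
-0.059395261806557097
-1.1716227542696607
0.24800279569070061
0.42548052230535727
0.957241616140031
-0.46257073830134154
0.15614189901422887
-0.50115453984953262
1.0698731008194304
-0.40448626538856269
-0.54664072866979641
-0.46520572012031874
-1.4645117845632947
-0.98843994446232442
-0.18606509616446126
0.63165263620671164
-0.34081177080056874
-0.10579692660516506
-0.24416169663159679
0.86137727932391084
0.99516610661125648
-0.41743913861339532
-1.5876288433622985
-0.44356537830709797
0.58311624332864365
0.70191302136708655
0.56892368541336791
2.0094928514326962
2.15604033420618
0.40018083041572994
-1.0318697578904128
-2.0010269898211792
-1.0408398801331193
-1.10715348946626
-1.4682870339716456
-1.09558526634294
-2.1043466118066521
-2.5964831757785669
-0.67978789055459288
0.40792961483898049
0.76257335584274366
-1.2982767471728538
0.15463001489411521
-1.9780492869299213
-2.6948003806975738
-2.182005919630928
-2.5947113761015155
-2.2253368801451576
-2.2952896521845569
-3.0289256290616473
-1.0641578901334485
-1.7048417709190375
0.038266135192745576
0.34004190994742695
1.0896794727303927
-0.19049118536267839
-0.42120045181692078
1.0701060242494473
-1.06403628810207
-2.2286789634208222
0.027053870988872797
1.4074226569573742
-0.24957587368330059
1.3583544767995741
0.076961731474301742
-0.6106703859283622
-0.014646961915838808
-1.2920838175530116
-0.83415930641841396
-0.67125465113686544
-0.12466840350869224
-1.6617782917534483
-2.1908424493738856
-1.1023970281818574
-1.5340101393615699
-0.60784723841691179
0.63878357775996841
0.43821546534819633
-0.23802239378755169
-1.501674674070379
-1.944620566108701
-1.2368637646299512
-1.4262078583385462
-0.88879000601890779
-1.9061047595053173
-1.1490975399305654
0.050365599726911681
0.10301055927815791
-0.48152870343542087
-0.17413514674297623
-0.73833262607195171
0.20932444511044185
0.61273490297661493
0.95342678182112572
0.06950457946328259
-0.97822333218521662
-0.66038098723348293
-0.43009509707057519
0.039398576246639283
-0.20019001516152143
1.9886482599754831
1.7723546998025148
1.8950818451961302
1.2866559522753755
1.910793889275169
0.67920723591865673
1.6899552051030833
3.3315273418981715
1.8836502820474779
1.1123882370706648
0.328497452123033
1.235835289793811
0.19132759365663976
0.82525264317938618
-0.2642664826524988
0.88314481000356104
-0.69869240037110969
0.81968436625648256
1.2529513898036946
0.53430519775732921
0.17829140897081988
1.1722198908312869
0.56267579343235496
0.42078002938060149
-0.36415880118032673
2.4768836070882845
2.6188733374807756
0.58202690088185371
-0.38485938166165823
-0.43312962348412593
1.2474988473506636
-0.33028836700178976
-1.6548223076465316
-1.9200879445208132
-1.5150123245388158
-1.3142565253346621
-1.4746569783929249
1.6373499498813961
0.78159909345765011
-1.4364183419958203
-1.1040790350949687
-2.1880126728382789
-0.80516471972663928
-2.3929790008652878
-0.38741695186269198
-1.2536100558871552
-0.51000847424738693
1.0685655362527271
1.6248702549420821
-0.70743286702111829
-0.71637386382130042
-1.4944437286066274
-1.2379626724111699
-1.9473372487750056
-0.65386664092342128
-0.17875174979932953
0.37131609432693236
-1.7579985810402976
-0.65799751822449326
-0.37558176608297611
-0.64832716746413277
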