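0
0.068542532802860531
-1.1834115786215267
-2.7492970963603485
-2.0756000555031955
-2.5141414436985663
-1.2895140139949743
-0.89544973687410756
-3.0239363926705636
-3.4005936883608023
-4.4591723103010148
-4.7547619801881149
-4.5940674549418858
-3.7309751676946648
-5.2016612983214667
-6.4051202090239858
-6.8292584307279443
-7.9586889901029547
-8.870341659402774
-8.3579205854565579
-9.9856968858682595
-11.227290053607076
-8.7707979451415188
-10.526180838026157
-11.592133423587242
-11.443939676805341
-12.12919138733019
-11.635803641614826
-11.677686587599899
-10.683045596502854
-10.74853560972279
-9.5165848156073487
-9.4339701886890914
-9.5348326056922179
-9.8360156136012424
-9.6278049173747657
-8.9348158947166247
-8.9306741763754385
-8.0587619158505568
-7.3752426096668877
-7.0458570180201345
-7.1353465808332528
-8.0221513434775638
-8.9699730247319334
-8.0627498266651969
-6.7517204067614189
-8.4914756535758382
-6.3488414545049032
-6.5971991961764687
-7.2174775447041792
-7.3252240312872257
-9.0028818947217744
-10.128718564301673
-9.5207231855827725
-9.806508900599292
-9.1422344300135414
-9.171483809510562
-7.920559484409317
-9.0503434835843404
-9.0762320094977689
-9.9498646088048019
-10.178016049979195
-9.4988045876321685
-8.5936972180112932
-8.5931238806929837
-8.0761280932378074
-9.5482928019119768
-10.169318015667777
-9.2420602786369397
-8.3015796806989268
-9.4601456883973452
-8.9834213314511739
-10.624224189219472
-9.2725290315606532
-10.168455441840248
-10.645519801579189
-9.801124647707022
-9.1827701756700577
-10.087359644574388
-10.298076222454757
-8.7161886579853078
-8.441778967183712
-9.9523098941679518
-7.7288312496604421
-7.2823399372132709
-8.0024276248690089
-10.259316987135147
-11.500242136254698
-12.407361133003047
-12.573443442305079
-13.719302780891066
-13.69215758725775
-13.731907632003258
-11.031349201255686
-9.742348320148146
-9.6438661175459384
-10.273031742043999
-12.62277895752953
-14.610646101226685
-14.275126216967344
-12.760033802042066
-11.472320167310565
-12.309096911364682
-12.504499501070296
-12.089594169248141
-13.223468035713726
-12.359967729490949
-11.81189074849145
-10.694809079075647
-9.5582127037518383
-8.4951132994998755
-9.2773856349046202
-10.880863233185787
-10.307380045460867
-11.236767166693145
-12.093519259596281
-11.623391673310213
-11.753994583557065
-11.087869770237569
-9.0859190957691176
-9.2061322996849171
-10.073644955506865
-9.8135445038467619
-9.5958993223097604
-7.6586808502269532
-6.7582989790153407
-6.6814697310606981
-7.2006939652676039
-5.8008206048766562
-6.4532185287565387
-7.7629844433685609
-9.9709144218672421
-8.9079421903259011
-8.8472299378983639
-8.1110928796093873
-8.7386465060116443
-9.6919300409861595
-10.139304750923248
-10.315811497333065
-11.372232737993361
-9.7433776097820726
-8.4598324246908021
-5.7126474519014216
-5.6795191932078879
-5.1204314216353009
-4.1199641206280875
-3.8882542747642659
-2.8405573608526171
-2.9641444414466034
-4.0006881294665249
-4.1182821591878547
-3.5636220445152569
-3.2265293859432487
-4.7172723634869493
-5.5780056463040584
-5.1699337259302576
-5.5505518877263427
-5.5029006161226723
-4.7264549001425875
-6.0220721786839029
-5.8871824656838498
-6.1150824791624832
-6.6480740187311689
-6.2659574448630355
-7.935425001782793
-6.9855847070688633
-7.370642775807049
-7.181600603158059
-7.2215477074214798
-7.7386283683680386
-6.9782723381909229
-8.2756657803711384
-8.6836917398395403
-8.7454708539699979
-8.4255599346220649
-7.1167521789270118
-6.5184653161280037
-5.1119832501812148
-4.6911221879955338
-6.2945634895134965
-6.8592556227343895
-5.9905908369659215
-4.9190885186436315
-4.7759129288174433
-5.1483322827442199
-5.2176902492846233
-5.4848433345957082
-5.773524517185618
-4.8792006038577078
-6.0599572609373951
-6.2102289928726453
-5.647313652221019
-6.2996298080824715
-5.4462162336182844
-6.2244137143125515
-7.6232993875714001
-8.707579379361837
-7.0900469531064179
-4.5414505648267074
-3.7300365781886078
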