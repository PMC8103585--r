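eccentricity_mm,density_cells_per_mm2
0,200542.705208876
0.1,200615.718344263
0.2,200197.847033766
0.3,199373.500865202
0.4,198265.596899182
0.5,197013.757269151
0.6,195751.894911313
0.7,194590.081789206
0.8,193603.829075341
0.9,192831.558834691
1,192278.937588968
1.1,191927.460219472
1.2,191744.400897561
1.3,191691.795478284
1.4,191733.088996568
1.5,191837.065216808
1.6,191979.396928457
1.7,192142.51805043
1.8,192314.567747789
1.9,192488.011186269
2,192658.324547679
2.1,192822.931248709
2.2,192980.433776821
2.3,193130.106645269
2.4,193271.586370137
2.5,193404.694422397
2.6,193529.342264563
2.7,193645.483321238
2.8,193753.090006259
2.9,193852.143308213
3,193942.628308175
3.1,194024.532346175
3.2,194097.844308031
3.3,194162.55436185
3.4,194218.653865989
3.5,194266.135339106
3.6,194304.992451531
3.7,194335.220023496
3.8,194356.814025353
3.9,194369.771578198
4,194374.090954448
4.1,192756.753724022
4.2,191144.378449648
4.3,189537.066345106
4.4,187934.917103086
4.5,186338.028890323
4.6,184746.498343127
4.7,183160.420563273
4.8,181579.889114281
4.9,180004.996018053
5,178435.831751893
5.1,176872.485245886
5.2,175315.043880646
5.3,173763.593485428
5.4,172218.218336593
5.5,170679.001156438
5.6,169146.023112376
5.7,167619.363816465
5.8,166099.101325296
5.9,164585.312140208
6,163078.071207865
6.1,161577.451921155
6.2,160083.526120436
6.3,158596.36409511
6.4,157116.034585519
6.5,155642.60478518
6.6,154176.140343329
6.7,152716.705367788
6.8,151264.362428146
6.9,149819.172559247
7,148381.195264992
7.1,146950.48852243
7.2,145527.108786163
7.3,144111.110993034
7.4,142702.54856711
7.5,141301.473424949
7.6,139907.935981153
7.7,138521.985154194
7.8,137143.668372514
7.9,135773.031580901
8,134410.119247117
8.1,133054.974368802
8.2,131707.638480617
8.3,130368.151661656
8.4,129036.55254309
8.5,127712.878316062
8.6,126397.164739819
8.7,125089.446150074
8.8,123789.7554676
8.9,122498.124207045
9,121214.582485971
9.1,119939.159034105
9.2,118671.881202796
9.3,117412.774974686
9.4,116161.864973574
9.5,114919.174474482
9.6,113684.725413907
9.7,112458.538400259
9.8,111240.632724488
9.9,110031.026370881
10,108829.73602803
10.1,107636.777099976
10.2,106452.163717504
10.3,105275.908749606
10.4,104108.02381509
10.5,102948.519294339
10.6,101797.404341218
10.7,100654.686895112
10.8,99520.3736931054
10.9,98394.4702822835
11,97276.9810321654
11.1,96167.9091472518
11.2,95067.2566796907
11.3,93975.024542052
11.4,92891.2125202091
11.5,91815.8192863209
11.6,90748.842411911
11.7,89690.2783810383
11.8,88640.122603556
11.9,87598.3694284526
12,86565.0121572717
12.1,85540.0430576062
12.2,84523.4533766614
12.3,83515.2333548834
12.4,82515.3722396483
12.5,81523.8582990078
12.6,80540.6788354869
12.7,79565.8201999291
12.8,78599.2678053851
12.9,77641.0061410417
13,76691.0187861844
13.1,75749.2884241924
13.2,74815.7968565597
13.3,73890.5250169394
13.4,72973.4529852069
13.5,72064.560001538
13.6,71163.8244804977
13.7,70271.2240251373
13.8,69386.7354410928
13.9,68510.3347506851
14,67641.9972070144
14.1,66781.6973080472
14.2,65929.4088106923
14.3,65085.1047448611
14.4,64248.7574275094
14.5,63420.3384766572
14.6,62599.8188253832
14.7,61787.1687357898
14.8,60982.3578129366
14.9,60185.3550187377
15,59396.1286858207
15.1,58614.6465313436
15.2,57840.875670767
15.3,57074.7826315776
15.4,56316.3333669613
15.5,55565.4932694221
15.6,54822.2271843437
15.7,54086.4994234917
15.8,53358.2737784535
15.9,52637.5135340124
16,51924.1814814541
16.1,51218.2399318025
16.2,50519.650728983
16.3,49828.3752629091
16.4,49144.3744824923
16.5,48467.6089085706
16.6,47798.0386467545
16.7,47135.6234001885
16.8,46480.322482225
16.9,45832.0948290086
17,45190.8990119697
17.1,44556.6932502239
17.2,43929.4354228762
17.3,43309.0830812282
17.4,42695.5934608853
17.5,42088.9234937636
17.6,41489.0298199933
17.7,40895.8687997184
17.8,40309.3965247893
17.9,39729.5688303487
18,39156.3413063071
18.1,38589.669308709
18.2,38029.5079709854
18.3,37475.8122150944
18.4,36928.5367625452
18.5,36387.6361453079
18.6,35853.0647166046
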