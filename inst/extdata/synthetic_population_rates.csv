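sex,age,rate
women,50,0.002
women,51,0.0021909839977307943
women,52,0.002400205439156206
women,53,0.00262940585422883
women,54,0.002880493075077518
women,55,0.0031555571165346047
women,56,0.0034568875731264223
women,57,0.0037869926773372157
women,58,0.004148620177784768
women,59,0.0045447802110947545
women,60,0.004978770357856094
women,61,0.005454203091219561
women,62,0.005975035846617943
women,63,0.00654560396290389
women,64,0.007170656769102847
women,65,0.007855397117162169
women,66,0.008605524689761461
women,67,0.009427283443672309
women,68,0.010327513583579242
women,69,0.011313708498984764
women,70,0.012394077138133248
women,71,0.013577612338145511
women,72,0.014874165680134506
women,73,0.016294529492385638
women,74,0.017850526684184697
women,75,0.019555109158057606
women,76,0.021422465619591557
women,77,0.0234681396822316
women,78,0.02570915925014024
women,79,0.028164178256084946
women,80,0.030853631934159846
women,81,0.03379990691981002
women,82,0.03702752759304704
women,83,0.04056336021595075
women,84,0.044436836563669015
women,85,0.048680198910388724
women,86,0.05332876840950687
women,87,0.05842123910196052
women,88,0.06400000000000003
women,89,0.07011148792738545
women,90,0.07680657405299862
women,91,0.08414098733532258
women,92,0.09217577840248059
women,93,0.10097782772910736
women,94,0.1106204023400456
women,95,0.12118376567479093
women,96,0.13275584568911267
women,97,0.14543296675503217
women,98,0.15932065145139498
women,99,0.17453449891902598
women,100,0.1912011470917742
men,50,0.0032
men,51,0.003514226161128901
men,52,0.0038593079723633667
men,53,0.004238275325103962
men,54,0.004654455632983575
men,55,0.005111503047263956
men,56,0.005613430541057841
men,57,0.006164645144082945
men,58,0.006769986637316416
men,59,0.007434770047297008
men,60,0.008164832313183969
men,61,0.00896658353631928
men,62,0.009847063262275288
men,63,0.010814002289555973
men,64,0.011875890547645448
men,65,0.01304205164038721
men,66,0.014322724709200882
men,67,0.015729154334912836
men,68,0.017273689267557735
men,69,0.01896989085101966
men,70,0.020832652094504085
men,71,0.022878328436313457
men,72,0.02512488134806
men,73,0.027592036040191257
men,74,0.03030145465351613
men,75,0.033276926457389826
men,76,0.03654457672453807
men,77,0.040133096116485634
men,78,0.044073992593642024
men,79,0.048401868061868206
men,80,0.053154722184539586
men,81,0.058374286027639916
men,82,0.06410638846736047
men,83,0.07040135857734071
men,84,0.077314467528596
men,85,0.08490641388210719
men,86,0.09324385653504351
men,87,0.10239999999999996
men,88,0.11245523715612481
men,89,0.1234978551156277
men,90,0.13562481040332672
men,91,0.14894258025547435
men,92,0.16356809751244655
men,93,0.17962977731385082
men,94,0.1972686446106541
men,95,0.21663957239412526
men,96,0.23791264151350416
men,97,0.26127463402188683
men,98,0.286930673162217
men,99,0.31510602439280905
men,100,0.3460480732657909
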