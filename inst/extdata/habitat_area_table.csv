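species,level,area_now_km2,area_2050_km2,area_2070_km2,printed_change_2050_pct,printed_change_2070_pct
Capricornis milneedwardsi,high,54876,50138,27868,-8.63,-49.21
Capricornis milneedwardsi,medium,170466,179324,174466,5.19,2.34
Capricornis milneedwardsi,low,467156,568799,526289,21.75,12.65
Naemorhedus griseus,high,369149,170345,92282,-53.85,-75.00
Naemorhedus griseus,medium,640326,493868,397301,-22.87,-37.95
Naemorhedus griseus,low,1834674,1400069,1167314,-23.68,-36.37
Elaphodus cephalophus,high,213434,236695,76661,10.89,-64.08
Elaphodus cephalophus,medium,372400,366222,306692,-1.65,-17.64
Elaphodus cephalophus,low,735084,738912,676538,0.52,-7.96
Hydropotes inermis,high,1004282,958594,435657,-4.54,-56.62
Hydropotes inermis,medium,647448,789096,1158562,21.87,78.94
Hydropotes inermis,low,2014916,2081083,1850296,3.28,-8.17
Muntiacus reevesi,high,82783,11159,5184,-86.52,-93.73
Muntiacus reevesi,medium,249809,58842,29950,-76.45,-88.01
Muntiacus reevesi,low,606564,330524,241320,-45.51,-60.21
Muntiacus vaginalis,high,45199,132459,120919,193.05,167.52
Muntiacus vaginalis,medium,131419,208282,189466,58.48,44.16
Muntiacus vaginalis,low,479220,443652,392290,-7.42,-18.13
Rusa unicolor,high,414874,694872,770772,67.48,85.78
Rusa unicolor,medium,1074348,1518966,1760765,41.38,63.89
Rusa unicolor,low,1969101,2364065,2512421,20.05,27.59
Sus scrofa,high,645192,609309,522649,-5.56,-18.99
Sus scrofa,medium,1665352,1598482,1439938,-4.01,-13.53
Sus scrofa,low,1715613,2010754,2047950,17.20,19.37
Panthera tigris amoyensis,high,240184,169345,85496,-29.49,-64.40
Panthera tigris amoyensis,medium,962382,904320,716603,-6.03,-25.53
Panthera tigris amoyensis,low,2176002,2665639,2829683,22.50,30.04
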