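time_h,species,value,replicate,excluded
1,X,0.719581113478,1,FALSE
3,X,2.22738822915095,1,TRUE
6,X,3.62953745923299,1,FALSE
12,X,6.77638252335076,1,FALSE
24,X,10.2764832668017,1,FALSE
48,X,14.0231206372799,1,FALSE
72,X,13.9406093451968,1,FALSE
1,X,0.735055814790015,2,FALSE
3,X,2.30988027360012,2,TRUE
6,X,3.79681042656751,2,FALSE
12,X,6.99065788648206,2,FALSE
24,X,9.20338782195821,2,FALSE
48,X,14.3826592373375,2,FALSE
72,X,11.3221814112647,2,FALSE
1,X,0.726023474972024,3,FALSE
3,X,2.06769645946539,3,TRUE
6,X,3.56679558118398,3,FALSE
12,X,6.6718205993608,3,FALSE
24,X,9.18245631717615,3,FALSE
48,X,10.1663349108604,3,FALSE
72,X,12.8937944853191,3,FALSE
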