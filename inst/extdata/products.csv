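product_no,name,abv,ibu,srm,og,fg
1,Imperial Black IPA,12.2,150,35,1.098,1.013
2,Guinness Extra Stout,5.1,40,40,1.070,1.034
3,Atlantic IPA Ale,8.4,80,13,1.074,1.013
4,Tokyo Rising Sun,15.4,85,71,1.125,1.023
5,Punk Monk,6.2,60,8.5,1.056,1.010
6,Santa Paws,4.7,35,22,1.048,1.013
7,Sunmaid Stout,11.1,50,100,1.102,1.026
8,Vice Bier,4.4,25,15,1.043,1.010
9,Blitz Berliner Weisse,4.3,8,4.5,1.040,1.007
10,Jasmine IPA,6.3,40,17.5,1.060,1.014
11,No Label,4.5,25,5,1.043,1.009
12,Monk Hammer,7.5,250,7.5,1.065,1.010
13,Science IPA,5.2,45,47,1.050,1.011
14,Tropic Thunder,7.5,25,86.36,1.074,1.020
15,Blonde Export Stout,7.7,55,8,1.075,1.020
16,Indie Pale Ale,4.8,30,8,1.044,1.008
17,Paradox Islay,14.2,40,127,1.112,1.015
18,Funk X Punk,7.2,42,12,1.058,1.004
19,Atlantic IPA Ale,8.4,80,28,1.074,1.013
20,Libertine Porter,6.5,45,109.5,1.067,1.020
21,Kozel Dark,4.6,35.09,21.87,1.042,1.007
22,Punk IPA,5.6,40,7.6,1.053,1.011
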