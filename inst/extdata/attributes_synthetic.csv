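name,alpha_acid,potential,colour,fermentability,attenuation
Cascade,0.055,NA,NA,NA,NA
Chinook,0.130,NA,NA,NA,NA
Northern Brewer,0.085,NA,NA,NA,NA
Magnum,0.120,NA,NA,NA,NA
Fuggles,0.045,NA,NA,NA,NA
Pale Malt (UK),NA,1.038,3,1.0,NA
Caramel/Crystal Malt,NA,1.034,60,0.2,NA
Cara-Pils/Dextrine,NA,1.033,1.5,0.0,NA
Biscuit Malt,NA,1.036,23,0.85,NA
Wheat Malt (Belgium),NA,1.038,2,1.0,NA
Chocolate Malt (UK),NA,1.034,450,0.3,NA
Munich Malt,NA,1.037,9,1.0,NA
Pilsner (German),NA,1.037,1.6,1.0,NA
Roasted Barley,NA,1.025,300,0.3,NA
Barley Flaked,NA,1.032,2,0.8,NA
Safale S-04,NA,NA,NA,NA,0.75
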