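name,category,stock_amount,unit
Cascade,hop,100,g
Chinook,hop,100,g
Northern Brewer,hop,100,g
Magnum,hop,40,g
Fuggles,hop,50,g
Pale Malt (UK),fermentable,7,kg
Caramel/Crystal Malt,fermentable,1,kg
Cara-Pils/Dextrine,fermentable,1,kg
Biscuit Malt,fermentable,0.5,kg
Wheat Malt (Belgium),fermentable,2,kg
Chocolate Malt (UK),fermentable,0.5,kg
Munich Malt,fermentable,3,kg
Pilsner (German),fermentable,5,kg
Roasted Barley,fermentable,0.5,kg
Barley Flaked,fermentable,0.5,kg
Safale S-04,yeast,11,mL
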