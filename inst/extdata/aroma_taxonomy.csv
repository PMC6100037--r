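descriptor,primary_series,secondary_series
apple,fruity,apple
citrus,fruity,citrus
orange,fruity,orange
lemon,fruity,lemon
grape,fruity,grape
banana,fruity,banana
strawberry,fruity,strawberry
pineapple,fruity,pineapple
fruity_placeholder_1,fruity,fruity_placeholder_1
fruity_placeholder_2,fruity,fruity_placeholder_2
fruity_placeholder_3,fruity,fruity_placeholder_3
fruity_placeholder_4,fruity,fruity_placeholder_4
fruity_placeholder_5,fruity,fruity_placeholder_5
fruity_placeholder_6,fruity,fruity_placeholder_6
fruity,fruity,
rose,floral,rose
geranium,floral,geranium
violet,floral,violet
lavender,floral,lavender
orange_flower,floral,orange_flower
floral_placeholder_1,floral,floral_placeholder_1
floral_placeholder_2,floral,floral_placeholder_2
floral_placeholder_3,floral,floral_placeholder_3
floral_placeholder_4,floral,floral_placeholder_4
floral_placeholder_5,floral,floral_placeholder_5
floral_placeholder_6,floral,floral_placeholder_6
floral_placeholder_7,floral,floral_placeholder_7
floral_placeholder_8,floral,floral_placeholder_8
flower,floral,
honey,sweet,honey
marshmallow,sweet,marshmallow
sweet_placeholder_1,sweet,sweet_placeholder_1
sweet_placeholder_2,sweet,sweet_placeholder_2
sweet_placeholder_3,sweet,sweet_placeholder_3
sweet,sweet,
green,herbaceous,
grass,herbaceous,
leafy,herbaceous,
herbaceous,herbaceous,
cut_grass,herbaceous,
spice,spicy,
pepper,spicy,
clove,spicy,
roasted,roasty,
toasted,roasty,
nutty,roasty,
fatty,fatty,
waxy,fatty,
tallow,fatty,
earthy,earthy,
mushroom,earthy,
musty,earthy,
balsamic,balsamic,
resin,balsamic,
pine,balsamic,
solvent,solvent,
ethereal,solvent,
varnish,solvent,
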