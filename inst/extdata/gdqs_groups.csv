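group_id,name,assessment_mode,reporting_group_id
whole_grains,Whole grains,cube,whole_grains
refined_grains,Refined grains and baked goods,cube,refined_grains
deep_orange_tubers,Deep orange tubers,cube,deep_orange_tubers
white_roots_tubers,White roots and tubers,cube,white_roots_tubers
legumes,Legumes,cube,legumes
nuts_seeds,Nuts and seeds,cube,nuts_seeds
fish_shellfish,Fish and shellfish,cube,fish_shellfish
poultry_game_meat,Poultry and game meat,cube,poultry_game_meat
red_meat,Red meat,cube,red_meat
processed_meat,Processed meat,cube,processed_meat
eggs,Eggs,cube,eggs
hf_dairy_cheese,High fat dairy: hard cheese,cube,high_fat_dairy
hf_dairy_other,High fat dairy: other,cube,high_fat_dairy
low_fat_dairy,Low fat dairy,cube,low_fat_dairy
deep_orange_fruits,Deep orange fruits,cube,deep_orange_fruits
citrus_fruits,Citrus fruits,cube,citrus_fruits
other_fruits,Other fruits,cube,other_fruits
dark_green_leafy_veg,Dark green leafy vegetables,cube,dark_green_leafy_veg
deep_orange_veg,Deep orange vegetables,cube,deep_orange_veg
cruciferous_veg,Cruciferous vegetables,cube,cruciferous_veg
other_veg,Other vegetables,cube,other_veg
liquid_oils,Liquid oils,oil_algorithm,liquid_oils
juice,Juice,cube,juice
ssb,Sugar-sweetened beverages,cube,ssb
sweets_ice_cream,Sweets and ice cream,cube,sweets_ice_cream
purchased_deep_fried,Purchased deep fried foods,cube,purchased_deep_fried
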