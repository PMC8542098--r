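group_id,category,points,role
whole_grains,low,0,healthy
whole_grains,middle,1,healthy
whole_grains,high,2,healthy
refined_grains,low,2,unhealthy
refined_grains,middle,1,unhealthy
refined_grains,high,0,unhealthy
deep_orange_tubers,low,0,healthy
deep_orange_tubers,middle,1,healthy
deep_orange_tubers,high,2,healthy
white_roots_tubers,low,2,unhealthy
white_roots_tubers,middle,1,unhealthy
white_roots_tubers,high,0,unhealthy
legumes,low,0,healthy
legumes,middle,1,healthy
legumes,high,2,healthy
nuts_seeds,low,0,healthy
nuts_seeds,middle,1,healthy
nuts_seeds,high,2,healthy
fish_shellfish,low,0,healthy
fish_shellfish,middle,1,healthy
fish_shellfish,high,2,healthy
poultry_game_meat,low,0,healthy
poultry_game_meat,middle,1,healthy
poultry_game_meat,high,2,healthy
red_meat,low,0,unhealthy_in_excess
red_meat,middle,2,unhealthy_in_excess
red_meat,high,0,unhealthy_in_excess
processed_meat,low,2,unhealthy
processed_meat,middle,1,unhealthy
processed_meat,high,0,unhealthy
eggs,low,0,healthy
eggs,middle,1,healthy
eggs,high,2,healthy
high_fat_dairy,low,0,healthy
high_fat_dairy,middle,1,healthy
high_fat_dairy,high,2,healthy
high_fat_dairy,very_high,1,healthy
low_fat_dairy,low,0,unhealthy_in_excess
low_fat_dairy,middle,2,unhealthy_in_excess
low_fat_dairy,high,0,unhealthy_in_excess
deep_orange_fruits,low,0,healthy
deep_orange_fruits,middle,1,healthy
deep_orange_fruits,high,2,healthy
citrus_fruits,low,0,healthy
citrus_fruits,middle,1,healthy
citrus_fruits,high,2,healthy
other_fruits,low,0,healthy
other_fruits,middle,1,healthy
other_fruits,high,2,healthy
dark_green_leafy_veg,low,0,healthy
dark_green_leafy_veg,middle,1,healthy
dark_green_leafy_veg,high,2,healthy
deep_orange_veg,low,0,healthy
deep_orange_veg,middle,1,healthy
deep_orange_veg,high,2,healthy
cruciferous_veg,low,0,healthy
cruciferous_veg,middle,1,healthy
cruciferous_veg,high,2,healthy
other_veg,low,0,healthy
other_veg,middle,1,healthy
other_veg,high,2,healthy
liquid_oils,low,0,healthy
liquid_oils,middle,1,healthy
liquid_oils,high,2,healthy
juice,low,2,unhealthy
juice,middle,1,unhealthy
juice,high,0,unhealthy
ssb,low,2,unhealthy
ssb,middle,1,unhealthy
ssb,high,0,unhealthy
sweets_ice_cream,low,2,unhealthy
sweets_ice_cream,middle,1,unhealthy
sweets_ice_cream,high,0,unhealthy
purchased_deep_fried,low,2,unhealthy
purchased_deep_fried,middle,1,unhealthy
purchased_deep_fried,high,0,unhealthy
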