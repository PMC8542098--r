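group_id,mean_density,representative_foods
whole_grains,0.65,Maize on cob;Whole grain bread;Whole maize grains;Whole-grain tortilla;Whole wheat roti/chapati;Oats;Whole flour injera;Nshima;Pearl millet roti/chapati
refined_grains,0.62,White rice;White bread;Pasta;Biscuits;Wheat roti/chapati;Tortilla;Sweet bread;Refined flour injera;Ugali;Fritters
deep_orange_tubers,0.65,Orange sweet potato
white_roots_tubers,0.78,Potatoes;French fries;White sweet potatoes;Plantain;Cassava;Yam;Ginger;Taro;Yam bean
legumes,0.80,Cowpeas;Lentils;Soybean;Kidney beans;Soymilk;Peas;Mung beans;Black beans;Pinto beans;Chickpeas
nuts_seeds,0.68,Peanuts/groundnuts;Sesame seeds;Peanut butter;Almonds;Sunflower seeds;Jackfruit seeds;Cowpea seeds;Cacao seeds;Job's tears;Cumin seeds
fish_shellfish,0.57,Tilapia;Tuna;Catfish;Carp;Mullet;Perch;Mackerel;Orangefin barb;Sea fish;Unspecified fish
poultry_game_meat,0.83,Chicken average cut;Chicken leg;Chicken breast;Chicken wings;Duck;Fowl;Buffalo;Rat;Chicken thigh;Donkey
red_meat,0.87,Beef;Pork;Goat;Mutton;Liver;Beef/goat stomach;Beef entrails;Pork ribs;Lamb;Pork organs
processed_meat,0.81,Smoked/dried beef;Ham;Pork sausage;Turkey ham;Burger meat;Turkey sausage;Dried pork;Smoked/dried goat meat;Chorizo;Bratwurst
eggs,0.6,Chicken eggs
hf_dairy_cheese,0.84,Hard cheese (unspecified);Cheddar cheese
hf_dairy_other,1.02,Whole milk;Sour milk;Buffalo milk;Whole-milk yogurt;Curd;Whole-milk drinkable yogurt;Oaxaca cheese;Soft cheese
low_fat_dairy,0.96,Low fat milk;Low fat yogurt;Skimmed buffalo milk;Low fat curd;Low fat cream cheese;Low fat cheese spread
deep_orange_fruits,0.73,Mango;Papaya;Cantaloupe;Nanche;Persimmon;Tree tomato
citrus_fruits,0.71,Orange;Lemon;Tangerine;Pomelo;Grapefruit
other_fruits,0.78,Banana;Watermelon;Apple;Avocado;Jack fruit;Grapes;Green papaya;Guava;Pineapple
dark_green_leafy_veg,0.70,Spinach;Sweet potato leaves;Pumpkin leaves;Cowpea leaves;Amaranth leaves;Kale;Baobab leaves;Moringa leaves;Jute mallow leaves
deep_orange_veg,0.85,Carrot;Pumpkin
cruciferous_veg,0.67,Cabbage;Broccoli;Cauliflower;Chinese cabbage
other_veg,0.68,Tomato;Onion;Eggplant;Water gourd;Cucumber;Okra;Sweet peppers;Fresh chili;Zucchini;Shallots
juice,1.05,Orange juice;Apple juice;Grape juice;Fruit juice (unspecified);Lemon juice;Bissap;Pineapple juice;Cranberry juice;Blackberry juice;Roselle drink
ssb,1.07,Soda/cola drink;Sweet flavored water;Energy drink;Sports drink;Industrial juice;Flavored/chocolate milk;Ovaltine;Zoom komm;Lassi
sweets_ice_cream,0.70,Sugar;Cake;Ice cream;Sugarcane;Honey;Hard candy;Jelly;Cookies;Sorghum cane;Jaggery
purchased_deep_fried,0.46,French fries;Deep fried doughnuts;Fritters;Fried onion;Chips;Churro;Fried chicken;Deep fried spring roll;Fried fish;Fried cake
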