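code,name,pca_excluded
meat,Meat and meat dishes,FALSE
fish,Fish and fish dishes,FALSE
egg,Egg and egg dishes,FALSE
milk_yoghurt,"Milk, yoghurt and plant-based alternatives",FALSE
cheese,Cheese,FALSE
bread,Bread,FALSE
porridge_cereals,Porridge and breakfast cereals,FALSE
pasta_rice,Pasta and rice (incl. composite dishes),FALSE
potatoes,Potatoes,FALSE
vegetables,Vegetables,FALSE
fruit,Fruit and berries,FALSE
legume,"Dried beans, lentils and legume dishes",FALSE
nuts_seeds,Nuts and seeds,FALSE
cake_dessert,Cake and dessert,FALSE
sweets_chocolate,Sweets and chocolate,FALSE
sugar_jam,Sugar and jam,FALSE
fat_oil,Fats and oils,FALSE
sauce,Sauces and dressings,FALSE
soup,Soups,FALSE
coffee,Coffee (incl. milk-based coffee drinks),FALSE
tea,Tea,FALSE
juice,Juice,FALSE
soft_drink,Soft drinks,FALSE
alcoholic_beverage,Alcoholic and alcohol-free beverages,FALSE
snacks,Savoury snacks,FALSE
other,Other and culinary ingredients,TRUE
supplements,Dietary supplements,TRUE
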