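category,food,n,df_pct,mrl,authority,olr_pct,median_all,median_above,max_conc
vegetable,Tomato,4250,13.7,3,national_standard,0.00,ND,0.03,2.46
vegetable,Leguminous vegetables,4305,17.1,0.5,national_standard,0.51,ND,0.05,2.13
vegetable,Eggplant,3965,6.10,3,national_standard,0.00,ND,0.03,0.80
vegetable,Balsam pear,1605,9.20,2,ministry_guideline,0.00,ND,0.04,1.20
vegetable,Pumpkin,136,5.10,2,ministry_guideline,0.00,ND,0.05,0.28
vegetable,Summer squash,2358,2.50,0.5,national_standard,0.00,ND,0.02,0.45
vegetable,Sponge gourd,223,6.30,2,ministry_guideline,0.00,ND,0.03,0.07
vegetable,Chinese wax gourd,124,3.20,2,ministry_guideline,0.00,ND,0.02,0.05
vegetable,Cucumber,3967,15.7,2,national_standard,0.00,ND,0.04,0.78
vegetable,Okra,12,0.00,0.5,ministry_guideline,0.00,ND,0.00,0.00
vegetable,Hot pepper,4465,9.90,2,national_standard,0.02,ND,0.04,2.29
vegetable,Chinese Cabbage,7423,6.30,0.5,ministry_guideline,0.86,ND,0.07,6.90
vegetable,Spinach,1864,7.20,0.5,ministry_guideline,1.61,ND,0.11,110
vegetable,Amaranth,318,10.7,0.5,ministry_guideline,0.94,ND,0.09,15.0
vegetable,Bok choy,957,10.1,0.5,ministry_guideline,1.88,ND,0.08,24.0
vegetable,Water spinach,1387,7.00,0.2,ministry_guideline,1.01,ND,0.05,3.61
vegetable,Chinese chive,1984,10.3,2,national_standard,0.60,ND,0.08,15.0
vegetable,Cabbage flowering stalk,1370,6.60,0.5,ministry_guideline,0.73,ND,0.06,2.73
vegetable,Coriander leaf,291,6.90,0.5,ministry_guideline,0.00,ND,0.03,0.13
vegetable,Endive lettuce,181,24.9,5,ministry_guideline,6.63,ND,0.09,22.0
vegetable,Romaine lettuce,154,20.1,5,ministry_guideline,2.60,ND,0.11,19.0
vegetable,Vinespinach,153,16.3,5,ministry_guideline,0.00,ND,0.05,2.60
vegetable,Celery stem,3007,18.4,0.5,ministry_guideline,3.29,ND,0.08,35.0
vegetable,Cabbage,3294,1.20,0.5,national_standard,0.03,ND,0.02,21.0
vegetable,Common spiderflower,3919,1.60,0.5,ministry_guideline,0.03,ND,0.03,3.10
vegetable,Leaf mustard,149,8.70,0.5,ministry_guideline,1.34,ND,0.04,0.65
vegetable,Crown daisy,203,8.40,5,ministry_guideline,0.00,ND,0.05,2.09
vegetable,Yam,1414,13.4,0.2,national_standard,3.25,ND,0.08,11.1
potato,Potato,2078,0.60,0.2,ministry_guideline,0.00,ND,0.03,0.12
vegetable,Lotus root,992,2.20,0.2,national_standard,0.10,ND,0.06,1.80
vegetable,Radish & Carrot,4520,0.80,0.2,national_standard,0.00,ND,0.03,0.19
vegetable,Lettuce stem,3825,11.2,5,national_standard,0.26,ND,0.12,21.0
vegetable,Manchurian wild rice,2079,3.10,0.2,ministry_guideline,0.10,ND,0.02,2.40
vegetable,Water chestnut,475,1.50,,,0.00,ND,0.02,0.21
vegetable,Arrowhead,271,2.60,,,0.00,ND,0.02,0.10
vegetable,Asparagus,35,0.00,0.5,national_standard,0.00,ND,0.00,0.01
vegetable,Allium vegetables,6276,2.80,2,ministry_guideline,0.03,ND,0.06,4.27
fruit,Watermelon,3500,6.00,2,national_standard,0.00,ND,0.03,0.40
fruit,Casaba,73,15.1,,,0.00,ND,0.02,0.30
fruit,Apple,2794,48.5,5,national_standard,0.00,ND,0.04,1.54
fruit,Pear,1767,19.9,3,national_standard,0.00,ND,0.04,2.90
fruit,Plum,72,16.7,0.5,national_standard,0.00,ND,0.04,0.09
fruit,Peach,2666,47.1,2,national_standard,0.23,ND,0.06,8.39
fruit,Chinese date,1410,41.9,0.5,national_standard,0.43,ND,0.05,1.10
fruit,Pomegranate,115,53.9,0.5,ministry_guideline,13.04,0.02,0.17,6.05
fruit,False sour cherry,347,35.7,0.5,national_standard,0.00,0.001,0.04,0.34
fruit,Bayberry,800,16.3,1,national_standard,0.25,ND,0.00,2.32
fruit,Loquat,58,5.20,3,national_standard,0.00,ND,0.10,0.30
fruit,Lychee,110,5.50,0.5,national_standard,0.00,ND,0.01,0.02
fruit,Banana,1598,33.8,2,national_standard,0.00,ND,0.05,1.67
fruit,Citrus,2634,16.7,5,national_standard,0.00,ND,0.03,1.20
fruit,Grape,3248,19.2,3,national_standard,0.00,ND,0.05,1.60
fruit,Strawberry,2635,20.4,0.5,national_standard,0.80,ND,0.05,2.64
fruit,Chinese kiwi fruit,780,32.1,5,national_standard,0.00,0.0006,0.07,2.59
mushroom,Shitake mushroom,5025,13.4,3,ministry_guideline,0.02,ND,0.03,4.47
mushroom,Button mushroom,1992,34.2,3,ministry_guideline,0.10,ND,0.10,4.85
mushroom,Oyster mushroom,4244,2.90,3,ministry_guideline,0.00,ND,0.03,0.63
mushroom,Columnar agroc,762,2.40,3,ministry_guideline,0.00,ND,0.04,1.20
mushroom,Gold needle mushroom,3741,9.50,3,ministry_guideline,0.00,ND,0.05,2.13
mushroom,King oyster mushroom,471,1.30,3,ministry_guideline,0.00,ND,0.03,0.08
mushroom,Straw mushroom,363,13.8,3,ministry_guideline,0.00,ND,0.04,0.41
mushroom,Wood ear fungus,629,6.70,3,ministry_guideline,0.48,ND,0.13,35.4
mushroom,Silver ear fungus,48,2.10,3,ministry_guideline,0.00,ND,0.01,0.01
cereal,Rice,498,2.20,2,national_standard,0.20,ND,0.02,5.20
cereal,Wheat,410,13.2,0.5,national_standard,0.73,ND,0.03,0.94
tea,Tea,470,0.90,5,national_standard,0.00,ND,0.02,0.04
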