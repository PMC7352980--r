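id,ESR_001,ESR_002,ESR_003,ESR_004,ESR_005,ESR_006,ESR_007,ESR_008,VDR_001,VDR_002,VDR_003,VDR_004,VDR_005,VDR_006,VDR_007,VDR_008,CTSD_001,CTSD_002,CTSD_003,CTSD_004,CTSD_005,CTSD_006,CTSD_007,CTSD_008
ESR_001,2.000000,0.553806,0.530984,0.635234,0.680229,0.566803,0.582341,0.383443,0.464689,0.429320,0.493487,0.513067,0.363675,0.555419,0.341890,0.430467,0.389766,0.483576,0.440671,0.577626,0.386604,0.416330,0.533745,0.421272
ESR_002,0.602764,2.000000,0.561980,0.586551,0.780951,0.424019,0.655560,0.312798,0.417354,0.525296,0.449428,0.499878,0.547720,0.635359,0.633327,0.334476,0.513407,0.445626,0.398282,0.376333,0.387027,0.577840,0.515353,0.555123
ESR_003,0.571660,0.434309,2.000000,0.771840,0.396607,0.414593,0.707544,0.371249,0.503101,0.292945,0.463631,0.374732,0.486340,0.326082,0.459700,0.484710,0.375514,0.671711,0.403798,0.408867,0.500481,0.602494,0.432624,0.602763
ESR_004,0.352800,0.507174,0.686809,2.000000,0.481771,0.478906,0.454168,0.638229,0.578918,0.602051,0.397430,0.306487,0.502784,0.346423,0.442430,0.418364,0.148561,0.501085,0.445023,0.469575,0.454305,0.496510,0.399489,0.533821
ESR_005,0.474022,0.808085,0.515362,0.372321,2.000000,0.418195,0.645433,0.554555,0.360658,0.527830,0.483193,0.468446,0.613371,0.386476,0.494606,0.403038,0.480829,0.537196,0.361941,0.506254,0.501027,0.445671,0.519754,0.346336
ESR_006,0.039034,0.639084,0.581355,0.594225,0.658841,2.000000,0.667498,0.527322,0.490919,0.436430,0.476519,0.418942,0.461594,0.355135,0.453367,0.353868,0.276201,0.688628,0.455284,0.496564,0.342346,0.334778,0.425919,0.460951
ESR_007,0.766822,0.134583,0.509462,0.343700,0.272096,0.541101,2.000000,0.527148,0.457641,0.319589,0.424867,0.472735,0.269916,0.391883,0.438112,0.488553,0.465998,0.446896,0.455563,0.433316,0.536364,0.405929,0.350031,0.345566
ESR_008,0.639460,0.691388,0.808017,0.660575,0.616557,0.388471,0.662920,2.000000,0.530601,0.507871,0.329739,0.333540,0.480040,0.433316,0.582911,0.434338,0.576170,0.413134,0.415756,0.444237,0.495653,0.565893,0.395964,0.540374
VDR_001,0.360114,0.382452,0.319182,0.435184,0.427494,0.397349,0.413688,0.638823,2.000000,0.635541,0.357811,0.652868,0.698118,0.288455,0.447159,0.512968,0.472599,0.395371,0.590499,0.434350,0.450249,0.417775,0.377916,0.359249
VDR_002,0.449781,0.380038,0.458856,0.631790,0.343651,0.478886,0.459419,0.477088,0.711628,2.000000,0.608388,0.420026,0.760432,0.627899,0.308849,0.555247,0.491606,0.423698,0.473906,0.340407,0.330461,0.417906,0.252649,0.392811
VDR_003,0.508996,0.384969,0.396561,0.402355,0.579774,0.423054,0.421301,0.352523,0.606668,0.798493,2.000000,0.642480,0.756869,0.402722,0.703160,0.574964,0.526031,0.333928,0.546905,0.508176,0.556173,0.371010,0.423816,0.341114
VDR_004,0.582916,0.253005,0.529945,0.407629,0.572211,0.424931,0.595651,0.359431,0.529351,0.654711,0.372817,2.000000,0.550454,0.607382,0.782638,0.657802,0.446223,0.512470,0.468963,0.367519,0.396648,0.340839,0.465046,0.349518
VDR_005,0.278176,0.469208,0.454776,0.310866,0.480105,0.499150,0.514277,0.446813,0.753486,0.391330,0.606126,0.737953,2.000000,0.792720,0.601468,0.734372,0.350498,0.396074,0.313949,0.337336,0.557998,0.505196,0.476522,0.506689
VDR_006,0.386780,0.393127,0.399868,0.446353,0.578640,0.332656,0.716928,0.567821,0.398464,0.441485,0.599614,0.553483,0.692088,2.000000,0.476705,0.325751,0.500740,0.563122,0.452016,0.503543,0.407247,0.377442,0.485347,0.425473
VDR_007,0.421971,0.586844,0.489456,0.530132,0.371941,0.427418,0.378443,0.517536,0.660701,0.828215,0.431601,0.678639,0.585224,0.512424,2.000000,0.834454,0.567303,0.454816,0.514632,0.339047,0.398245,0.326119,0.359924,0.426704
VDR_008,0.300316,0.521636,0.463735,0.263575,0.535559,0.465391,0.523293,0.257547,0.513324,0.671230,0.617823,0.446797,0.676804,0.543839,0.582108,2.000000,0.314980,0.515528,0.494051,0.471993,0.447190,0.404294,0.420685,0.605660
CTSD_001,0.506300,0.508067,0.604221,0.370918,0.353913,0.594709,0.523023,0.253035,0.581345,0.695448,0.459912,0.363825,0.486224,0.532239,0.257758,0.427768,2.000000,0.147057,0.513439,0.480319,0.204755,0.386046,0.396253,0.621830
CTSD_002,0.515992,0.428687,0.344299,0.448893,0.499088,0.598534,0.372185,0.737745,0.430141,0.534773,0.469210,0.438803,0.509810,0.504745,0.312946,0.550157,0.429333,2.000000,0.481934,0.455093,0.496688,0.589349,0.651800,0.310277
CTSD_003,0.397623,0.463187,0.490471,0.511637,0.662527,0.328131,0.567017,0.501890,0.495463,0.427625,0.309796,0.467256,0.534971,0.395321,0.349819,0.419249,0.592708,0.556805,2.000000,0.685122,0.402516,0.457556,0.638430,0.504400
CTSD_004,0.538506,0.710780,0.355601,0.366916,0.461108,0.512737,0.503472,0.425205,0.356985,0.458683,0.469459,0.474500,0.364837,0.466169,0.561689,0.567489,0.380575,0.325856,0.479777,2.000000,0.550897,0.716185,0.388352,0.387879
CTSD_005,0.488564,0.370474,0.316665,0.458292,0.424326,0.404094,0.270280,0.659123,0.465343,0.410946,0.466890,0.387557,0.427654,0.278243,0.450313,0.611579,0.354933,0.436024,0.588007,0.363068,2.000000,0.800356,0.450217,0.576686
CTSD_006,0.490493,0.508964,0.372591,0.266843,0.692346,0.408709,0.366768,0.629058,0.558060,0.646080,0.563276,0.583125,0.330441,0.495265,0.338598,0.344895,0.251736,0.521676,0.365136,0.510646,0.454908,2.000000,0.311983,0.628628
CTSD_007,0.557725,0.706583,0.355790,0.462752,0.519434,0.380125,0.572719,0.493230,0.435293,0.183710,0.497117,0.394941,0.526029,0.537201,0.500013,0.346294,0.285548,0.566928,0.590647,0.379163,0.433652,0.332752,2.000000,0.345257
CTSD_008,0.443214,0.429100,0.410290,0.487452,0.488780,0.233320,0.402743,0.305771,0.565423,0.457280,0.550391,0.304712,0.481293,0.371184,0.253517,0.367699,0.301387,0.510211,0.524234,0.356487,0.497785,0.449311,0.530346,2.000000
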