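id,rs0001
ind001,TT
ind002,NA
ind003,GG
ind004,NA
ind005,GG
ind006,GG
ind007,GT
ind008,TT
ind009,GT
ind010,GG
ind011,GT
ind012,GG
ind013,NA
ind014,GG
ind015,GT
ind016,GT
ind017,NA
ind018,GG
ind019,NA
ind020,TT
ind021,GG
ind022,NA
ind023,NA
ind024,NA
ind025,NA
ind026,TT
ind027,NA
ind028,NA
ind029,TT
ind030,GG
ind031,GG
ind032,GG
ind033,TT
ind034,NA
ind035,TT
ind036,GT
ind037,GG
ind038,GG
ind039,GT
ind040,NA
ind041,GT
ind042,GG
ind043,GG
ind044,GG
ind045,NA
ind046,NA
ind047,NA
ind048,NA
ind049,GG
ind050,GG
ind051,GG
ind052,TT
ind053,TT
ind054,GT
ind055,NA
ind056,GT
ind057,GG
ind058,GT
ind059,GG
ind060,NA
ind061,GG
ind062,GG
ind063,NA
ind064,GG
ind065,GG
ind066,NA
ind067,GG
ind068,GG
ind069,GG
ind070,GG
ind071,GG
ind072,GT
ind073,TT
ind074,NA
ind075,NA
ind076,GT
ind077,GT
ind078,TT
ind079,GT
ind080,NA
ind081,NA
ind082,NA
ind083,GG
ind084,NA
ind085,TT
ind086,GG
ind087,TT
ind088,NA
ind089,NA
ind090,GT
ind091,GT
ind092,GT
ind093,NA
ind094,GT
ind095,NA
ind096,NA
ind097,GT
ind098,NA
ind099,GT
ind100,TT
ind101,NA
ind102,GT
ind103,GG
ind104,GT
ind105,GG
ind106,GG
ind107,GG
ind108,NA
ind109,GG
ind110,TT
ind111,GG
ind112,NA
ind113,NA
ind114,GT
ind115,GT
ind116,TT
ind117,NA
ind118,NA
ind119,NA
ind120,TT
ind121,GT
ind122,NA
ind123,TT
ind124,GG
ind125,GG
ind126,NA
ind127,GG
ind128,TT
ind129,NA
ind130,GT
ind131,GT
ind132,GT
ind133,GG
ind134,GG
ind135,NA
ind136,GT
ind137,NA
ind138,NA
ind139,TT
ind140,NA
ind141,GG
ind142,NA
ind143,GG
ind144,GT
ind145,GG
ind146,GT
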