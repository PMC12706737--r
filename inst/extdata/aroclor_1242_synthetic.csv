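"peak_id","fraction"
"PCB1",0.0045454545
"PCB2",0.00090909091
"PCB3",0.0045454545
"PCB4",0.033333333
"PCB5",0.0066666667
"PCB6",0.0066666667
"PCB7",0.0066666667
"PCB8",0.033333333
"PCB9",0.0066666667
"PCB10",0.0066666667
"PCB11",0.0066666667
"PCB12",0.0066666667
"PCB13",0.0066666667
"PCB14",0.0066666667
"PCB15",0.033333333
"PCB16",0.047115385
"PCB17",0.047115385
"PCB18+30",0.056538462
"PCB19",0.0094230769
"PCB20",0.0094230769
"PCB21+33",0.056538462
"PCB22",0.047115385
"PCB23",0.0094230769
"PCB24",0.0094230769
"PCB25",0.0094230769
"PCB26",0.0094230769
"PCB27",0.0094230769
"PCB28",0.047115385
"PCB29",0.0094230769
"PCB31",0.047115385
"PCB32",0.0094230769
"PCB34",0.0094230769
"PCB35",0.0094230769
"PCB36",0.0094230769
"PCB37",0.0094230769
"PCB38",0.0094230769
"PCB39",0.0094230769
"PCB40",0.0037878788
"PCB41",0.0037878788
"PCB42",0.0037878788
"PCB43",0.0037878788
"PCB44+47+65",0.026515152
"PCB45+51",0.0075757576
"PCB46",0.0037878788
"PCB48",0.0037878788
"PCB49+69",0.022727273
"PCB50+53",0.0075757576
"PCB52",0.018939394
"PCB54",0.0037878788
"PCB55",0.0037878788
"PCB56",0.0037878788
"PCB57",0.0037878788
"PCB58",0.0037878788
"PCB59+62+75",0.011363636
"PCB60",0.0037878788
"PCB61+70+74+76",0.045454545
"PCB63",0.0037878788
"PCB64",0.0037878788
"PCB66",0.018939394
"PCB67",0.0037878788
"PCB68",0.0037878788
"PCB71",0.0037878788
"PCB72",0.0037878788
"PCB73",0.0037878788
"PCB77",0.0037878788
"PCB78",0.0037878788
"PCB79",0.0037878788
"PCB80",0.0037878788
"PCB81",0.0037878788
"PCB82",0.0011428571
"PCB83+99",0.0068571429
"PCB84",0.0011428571
"PCB85+116",0.0022857143
"PCB86+87+97",0.0034285714
"PCB88+91",0.0022857143
"PCB89",0.0011428571
"PCB90+101+113",0.008
"PCB92",0.0011428571
"PCB93+95",0.0068571429
"PCB94",0.0011428571
"PCB96",0.0011428571
"PCB98",0.0011428571
"PCB100",0.0011428571
"PCB102",0.0011428571
"PCB103",0.0011428571
"PCB104",0.0011428571
"PCB105",0.0057142857
"PCB106",0.0011428571
"PCB107+124",0.0022857143
"PCB108",0.0011428571
"PCB109",0.0011428571
"PCB110+115",0.0068571429
"PCB111",0.0011428571
"PCB112",0.0011428571
"PCB114",0.0011428571
"PCB117",0.0011428571
"PCB118",0.0057142857
"PCB119",0.0011428571
"PCB120",0.0011428571
"PCB121",0.0011428571
"PCB122",0.0011428571
"PCB123",0.0011428571
"PCB125",0.0011428571
"PCB126",0.0011428571
"PCB127",0.0011428571
"PCB128+166",0.0011111111
"PCB129+138+163",0.0012962963
"PCB130",0.00018518519
"PCB131",0.00018518519
"PCB132",0.00018518519
"PCB133",0.00018518519
"PCB134+143",0.00037037037
"PCB135+151",0.00037037037
"PCB136",0.00018518519
"PCB137",0.00018518519
"PCB139+140",0.00037037037
"PCB141",0.00018518519
"PCB142",0.00018518519
"PCB144",0.00018518519
"PCB145",0.00018518519
"PCB146",0.00018518519
"PCB147+149",0.00037037037
"PCB148",0.00018518519
"PCB150",0.00018518519
"PCB152",0.00018518519
"PCB153+168",0.0011111111
"PCB154",0.00018518519
"PCB155",0.00018518519
"PCB156+157",0.00037037037
"PCB158",0.00018518519
"PCB159",0.00018518519
"PCB160",0.00018518519
"PCB161",0.00018518519
"PCB162",0.00018518519
"PCB164",0.00018518519
"PCB165",0.00018518519
"PCB167",0.00018518519
"PCB169",0.00018518519
"PCB170",0
"PCB171+173",0
"PCB172",0
"PCB174",0
"PCB175",0
"PCB176",0
"PCB177",0
"PCB178",0
"PCB179",0
"PCB180+193",0
"PCB181",0
"PCB182",0
"PCB183+185",0
"PCB184",0
"PCB186",0
"PCB187",0
"PCB188",0
"PCB189",0
"PCB190",0
"PCB191",0
"PCB192",0
"PCB194",0
"PCB195",0
"PCB196",0
"PCB197+200",0
"PCB198+199",0
"PCB201",0
"PCB202",0
"PCB203",0
"PCB204",0
"PCB205",0
"PCB206",0
"PCB207",0
"PCB208",0
"PCB209",0
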