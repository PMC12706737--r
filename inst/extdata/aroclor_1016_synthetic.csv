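"peak_id","fraction"
"PCB1",0.0090909091
"PCB2",0.0018181818
"PCB3",0.0090909091
"PCB4",0.039583333
"PCB5",0.0079166667
"PCB6",0.0079166667
"PCB7",0.0079166667
"PCB8",0.039583333
"PCB9",0.0079166667
"PCB10",0.0079166667
"PCB11",0.0079166667
"PCB12",0.0079166667
"PCB13",0.0079166667
"PCB14",0.0079166667
"PCB15",0.039583333
"PCB16",0.054807692
"PCB17",0.054807692
"PCB18+30",0.065769231
"PCB19",0.010961538
"PCB20",0.010961538
"PCB21+33",0.065769231
"PCB22",0.054807692
"PCB23",0.010961538
"PCB24",0.010961538
"PCB25",0.010961538
"PCB26",0.010961538
"PCB27",0.010961538
"PCB28",0.054807692
"PCB29",0.010961538
"PCB31",0.054807692
"PCB32",0.010961538
"PCB34",0.010961538
"PCB35",0.010961538
"PCB36",0.010961538
"PCB37",0.010961538
"PCB38",0.010961538
"PCB39",0.010961538
"PCB40",0.0031818182
"PCB41",0.0031818182
"PCB42",0.0031818182
"PCB43",0.0031818182
"PCB44+47+65",0.022272727
"PCB45+51",0.0063636364
"PCB46",0.0031818182
"PCB48",0.0031818182
"PCB49+69",0.019090909
"PCB50+53",0.0063636364
"PCB52",0.015909091
"PCB54",0.0031818182
"PCB55",0.0031818182
"PCB56",0.0031818182
"PCB57",0.0031818182
"PCB58",0.0031818182
"PCB59+62+75",0.0095454545
"PCB60",0.0031818182
"PCB61+70+74+76",0.038181818
"PCB63",0.0031818182
"PCB64",0.0031818182
"PCB66",0.015909091
"PCB67",0.0031818182
"PCB68",0.0031818182
"PCB71",0.0031818182
"PCB72",0.0031818182
"PCB73",0.0031818182
"PCB77",0.0031818182
"PCB78",0.0031818182
"PCB79",0.0031818182
"PCB80",0.0031818182
"PCB81",0.0031818182
"PCB82",0.00014285714
"PCB83+99",0.00085714286
"PCB84",0.00014285714
"PCB85+116",0.00028571429
"PCB86+87+97",0.00042857143
"PCB88+91",0.00028571429
"PCB89",0.00014285714
"PCB90+101+113",0.001
"PCB92",0.00014285714
"PCB93+95",0.00085714286
"PCB94",0.00014285714
"PCB96",0.00014285714
"PCB98",0.00014285714
"PCB100",0.00014285714
"PCB102",0.00014285714
"PCB103",0.00014285714
"PCB104",0.00014285714
"PCB105",0.00071428571
"PCB106",0.00014285714
"PCB107+124",0.00028571429
"PCB108",0.00014285714
"PCB109",0.00014285714
"PCB110+115",0.00085714286
"PCB111",0.00014285714
"PCB112",0.00014285714
"PCB114",0.00014285714
"PCB117",0.00014285714
"PCB118",0.00071428571
"PCB119",0.00014285714
"PCB120",0.00014285714
"PCB121",0.00014285714
"PCB122",0.00014285714
"PCB123",0.00014285714
"PCB125",0.00014285714
"PCB126",0.00014285714
"PCB127",0.00014285714
"PCB128+166",0
"PCB129+138+163",0
"PCB130",0
"PCB131",0
"PCB132",0
"PCB133",0
"PCB134+143",0
"PCB135+151",0
"PCB136",0
"PCB137",0
"PCB139+140",0
"PCB141",0
"PCB142",0
"PCB144",0
"PCB145",0
"PCB146",0
"PCB147+149",0
"PCB148",0
"PCB150",0
"PCB152",0
"PCB153+168",0
"PCB154",0
"PCB155",0
"PCB156+157",0
"PCB158",0
"PCB159",0
"PCB160",0
"PCB161",0
"PCB162",0
"PCB164",0
"PCB165",0
"PCB167",0
"PCB169",0
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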