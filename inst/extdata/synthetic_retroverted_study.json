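{
  "schema_version": 1,
  "films": [
    {
      "film_id": "film1",
      "side": "left",
      "scale_mm_per_unit": 1,
      "landmarks": {
        "left_teardrop": [62.1162199027821, 0.196394926736726],
        "right_teardrop": [-61.7775610588017, 0.100107335023958],
        "scj": [-0.067774053456458, 41.5625397861927],
        "ps": [0.257525565493997, -52.7008901810786]
      },
      "rim_points": [
        [27.8599075215323, 2.15495787579377],
        [27.991733072485, 3.7109995204202],
        [29.6102126008149, 5.54179294616893],
        [32.2719402408592, 8.48508581150544],
        [35.5419194847493, 12.3784300527773],
        [39.8535638550006, 16.3225785562491],
        [44.4330605151618, 20.2235662205643],
        [49.5670051649552, 24.2997222320036],
        [54.6811540671026, 27.9053156791872],
        [59.1880099629186, 31.5342273729704],
        [62.9731332665406, 33.5582998185916],
        [65.6594690988362, 33.9933734476669],
        [67.3859744120954, 33.948068845375],
        [67.220002895, 33.0236130223272],
        [66.3419720961409, 31.1413667536691],
        [63.5933260948449, 28.4968160689885],
        [60.804658398584, 25.4494617224124],
        [56.5884341512923, 20.5488628240764],
        [51.4035048694845, 16.8767295454582],
        [46.6364148673082, 12.419375861544],
        [41.4144725182025, 9.12155784461805],
        [36.1259677505706, 6.01023728370108],
        [33.4934652535356, 3.79591552407499],
        [30.1185375897512, 2.37766003489282]
      ],
      "provenance": "synthetic: true version -12.0 deg"
    },
    {
      "film_id": "film2",
      "side": "left",
      "scale_mm_per_unit": 1,
      "landmarks": {
        "left_teardrop": [61.9045454964937, 0.101535888575375],
        "right_teardrop": [-62.4146918709091, -0.247513791581733],
        "scj": [-0.0651539267654032, 49.4715351485671],
        "ps": [-0.180683489929471, -57.7323055114491]
      },
      "rim_points": [
        [28.8188118627484, 0.885407553497428],
        [28.7140913757053, 2.75027161466421],
        [29.4649375712264, 7.08156828486517],
        [31.8203735050586, 10.4956386117041],
        [35.4518830924988, 15.3219296586776],
        [39.6428428751032, 19.8885874596008],
        [44.5569059353461, 23.7173030101863],
        [49.5772625288121, 28.2206898414099],
        [54.7050397576973, 31.0163082434628],
        [58.7584255066125, 33.7044007439454],
        [62.7712739777613, 33.9402152152534],
        [65.5110802777391, 34.4810297230918],
        [67.1885355912864, 32.540258671004],
        [67.2020963352014, 30.2068889839851],
        [66.8517236903836, 26.7253264267855],
        [63.9111666734176, 22.4228534628196],
        [60.2791528225516, 18.0402874715034],
        [56.3806487078878, 13.6240208933672],
        [51.8406089491537, 9.35986854984409],
        [46.3903929625826, 5.48147296546674],
        [41.2641508192824, 1.96232327082965],
        [36.8226997406498, 0.104631109809664],
        [32.9484815950908, -0.749082893707524],
        [30.4475632090222, -0.649770013071247]
      ],
      "provenance": "synthetic: true version -12.0 deg"
    }
  ]
}
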