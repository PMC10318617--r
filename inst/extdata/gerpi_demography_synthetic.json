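{
  "populations": [
    {
      "id": "Ambodisakoana",
      "name": "Ambodisakoana",
      "tip": true
    },
    {
      "id": "Andobo",
      "name": "Andobo",
      "tip": true
    },
    {
      "id": "Antanambao",
      "name": "Antanambao",
      "tip": true
    },
    {
      "id": "gerpi",
      "name": "gerpi",
      "tip": false
    },
    {
      "id": "jollyae",
      "name": "jollyae",
      "tip": true
    },
    {
      "id": "marohita",
      "name": "marohita",
      "tip": true
    },
    {
      "id": "north",
      "name": "north",
      "tip": false
    },
    {
      "id": "outgroup",
      "name": "outgroup",
      "tip": false
    },
    {
      "id": "root",
      "name": "root",
      "tip": false
    },
    {
      "id": "Sahamamy",
      "name": "Sahamamy",
      "tip": true
    },
    {
      "id": "south",
      "name": "south",
      "tip": false
    },
    {
      "id": "south1",
      "name": "south1",
      "tip": false
    },
    {
      "id": "VohiposaSahafina",
      "name": "VohiposaSahafina",
      "tip": true
    }
  ],
  "edges": [
    {
      "child": "Ambodisakoana",
      "parent": "south1"
    },
    {
      "child": "Andobo",
      "parent": "north"
    },
    {
      "child": "Antanambao",
      "parent": "south"
    },
    {
      "child": "gerpi",
      "parent": "root"
    },
    {
      "child": "jollyae",
      "parent": "outgroup"
    },
    {
      "child": "marohita",
      "parent": "outgroup"
    },
    {
      "child": "north",
      "parent": "gerpi"
    },
    {
      "child": "outgroup",
      "parent": "root"
    },
    {
      "child": "Sahamamy",
      "parent": "north"
    },
    {
      "child": "south",
      "parent": "gerpi"
    },
    {
      "child": "south1",
      "parent": "south"
    },
    {
      "child": "VohiposaSahafina",
      "parent": "south1"
    }
  ],
  "theta": {
    "Ambodisakoana": 0.00029664,
    "Andobo": 0.000177984,
    "Antanambao": 0.00034608,
    "gerpi": 0.00059328,
    "jollyae": 0.0004944,
    "marohita": 0.0004944,
    "north": 0.00029664,
    "outgroup": 0.0004944,
    "root": 0.0007416,
    "Sahamamy": 0.00039552,
    "south": 0.00044496,
    "south1": 0.00039552,
    "VohiposaSahafina": 0.000736656
  },
  "tau": {
    "gerpi": 0.000896982857142857,
    "north": 0.000151851428571429,
    "outgroup": 0.000960548571428571,
    "root": 0.00159973714285714,
    "south": 0.000529714285714286,
    "south1": 0.000144788571428571
  },
  "migration_bands": [
    {
      "id": "Ambodisakoana->Antanambao",
      "source": "Ambodisakoana",
      "target": "Antanambao",
      "rate": 635.691169671752,
      "pair": "Antanambao~Ambodisakoana"
    },
    {
      "id": "Ambodisakoana->VohiposaSahafina",
      "source": "Ambodisakoana",
      "target": "VohiposaSahafina",
      "rate": 108.598857540019,
      "pair": "VohiposaSahafina~Ambodisakoana"
    },
    {
      "id": "Andobo->Sahamamy",
      "source": "Andobo",
      "target": "Sahamamy",
      "rate": 4045.3074433657,
      "pair": "Sahamamy~Andobo"
    },
    {
      "id": "Antanambao->Ambodisakoana",
      "source": "Antanambao",
      "target": "Ambodisakoana",
      "rate": 2022.65372168285,
      "pair": "Antanambao~Ambodisakoana"
    },
    {
      "id": "Antanambao->jollyae",
      "source": "Antanambao",
      "target": "jollyae",
      "rate": 80.9061488673139,
      "pair": "jollyae~Antanambao"
    },
    {
      "id": "jollyae->Antanambao",
      "source": "jollyae",
      "target": "Antanambao",
      "rate": 115.580212667591,
      "pair": "jollyae~Antanambao"
    },
    {
      "id": "jollyae->marohita",
      "source": "jollyae",
      "target": "marohita",
      "rate": 121.359223300971,
      "pair": "jollyae~marohita"
    },
    {
      "id": "marohita->jollyae",
      "source": "marohita",
      "target": "jollyae",
      "rate": 80.9061488673139,
      "pair": "jollyae~marohita"
    },
    {
      "id": "Sahamamy->Andobo",
      "source": "Sahamamy",
      "target": "Andobo",
      "rate": 12922.5098885293,
      "pair": "Sahamamy~Andobo"
    },
    {
      "id": "Sahamamy->VohiposaSahafina",
      "source": "Sahamamy",
      "target": "VohiposaSahafina",
      "rate": 54.2994287700093,
      "pair": "Sahamamy~VohiposaSahafina"
    },
    {
      "id": "VohiposaSahafina->Ambodisakoana",
      "source": "VohiposaSahafina",
      "target": "Ambodisakoana",
      "rate": 337.108953613808,
      "pair": "VohiposaSahafina~Ambodisakoana"
    },
    {
      "id": "VohiposaSahafina->Sahamamy",
      "source": "VohiposaSahafina",
      "target": "Sahamamy",
      "rate": 151.699029126214,
      "pair": "Sahamamy~VohiposaSahafina"
    }
  ]
}
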