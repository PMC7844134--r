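[
 {
  "class": "Alphaproteobacteria-like",
  "blocks": [
   {
    "name": "bchO",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "ppsR",
    "orientation": "reverse",
    "n_members": 1
   },
   {
    "name": "bchID",
    "orientation": "forward",
    "n_members": 2
   },
   {
    "name": "bchFNBHLM",
    "orientation": "forward",
    "n_members": 6
   },
   {
    "name": "lhaA-puhABC",
    "orientation": "forward",
    "n_members": 4
   },
   {
    "name": "puhE",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "acsF",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "crtF-bchCXYZ",
    "orientation": "forward",
    "n_members": 5
   },
   {
    "name": "bchP2G",
    "orientation": "forward",
    "n_members": 3
   },
   {
    "name": "pufBALMC",
    "orientation": "reverse",
    "n_members": 5
   },
   {
    "name": "aerR",
    "orientation": "forward",
    "n_members": 1
   }
  ]
 },
 {
  "class": "Betaproteobacteria-like",
  "blocks": [
   {
    "name": "aerR",
    "orientation": "reverse",
    "n_members": 1
   },
   {
    "name": "ppsR",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "acsF",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "bchFNBHLM",
    "orientation": "reverse",
    "n_members": 6
   },
   {
    "name": "bchP2G",
    "orientation": "reverse",
    "n_members": 3
   },
   {
    "name": "bchO",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "bchID",
    "orientation": "reverse",
    "n_members": 2
   },
   {
    "name": "crtF-bchCXYZ",
    "orientation": "forward",
    "n_members": 5
   },
   {
    "name": "puhE",
    "orientation": "reverse",
    "n_members": 1
   },
   {
    "name": "lhaA-puhABC",
    "orientation": "reverse",
    "n_members": 4
   },
   {
    "name": "pufBALMC",
    "orientation": "forward",
    "n_members": 5
   }
  ]
 },
 {
  "class": "Gammaproteobacteria-like",
  "blocks": [
   {
    "name": "acsF",
    "orientation": "reverse",
    "n_members": 1
   },
   {
    "name": "pufBALMC",
    "orientation": "forward",
    "n_members": 5
   },
   {
    "name": "puhE",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "lhaA-puhABC",
    "orientation": "forward",
    "n_members": 4
   },
   {
    "name": "bchFNBHLM",
    "orientation": "forward",
    "n_members": 6
   },
   {
    "name": "bchID",
    "orientation": "forward",
    "n_members": 2
   },
   {
    "name": "bchP2G",
    "orientation": "forward",
    "n_members": 3
   },
   {
    "name": "crtF-bchCXYZ",
    "orientation": "reverse",
    "n_members": 5
   },
   {
    "name": "bchO",
    "orientation": "reverse",
    "n_members": 1
   },
   {
    "name": "ppsR",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "aerR",
    "orientation": "forward",
    "n_members": 1
   }
  ]
 },
 {
  "class": "Acidiferrobacteraceae-like",
  "blocks": [
   {
    "name": "acsF",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "bchFNBHLM",
    "orientation": "forward",
    "n_members": 6
   },
   {
    "name": "bchP2G",
    "orientation": "forward",
    "n_members": 3
   },
   {
    "name": "bchID",
    "orientation": "forward",
    "n_members": 2
   },
   {
    "name": "ppsR",
    "orientation": "reverse",
    "n_members": 1
   },
   {
    "name": "aerR",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "crtF-bchCXYZ",
    "orientation": "forward",
    "n_members": 5
   },
   {
    "name": "pufBALMC",
    "orientation": "forward",
    "n_members": 5
   },
   {
    "name": "lhaA-puhABC",
    "orientation": "forward",
    "n_members": 4
   },
   {
    "name": "puhE",
    "orientation": "forward",
    "n_members": 1
   }
  ]
 },
 {
  "class": "Gemmatimonas-adjacent-transposed",
  "blocks": [
   {
    "name": "bchP2G",
    "orientation": "forward",
    "n_members": 3
   },
   {
    "name": "bchFNBHLM",
    "orientation": "reverse",
    "n_members": 6
   },
   {
    "name": "acsF",
    "orientation": "reverse",
    "n_members": 1
   },
   {
    "name": "lhaA-puhABC",
    "orientation": "forward",
    "n_members": 4
   },
   {
    "name": "puhE",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "pufBALMC",
    "orientation": "forward",
    "n_members": 5
   },
   {
    "name": "crtF-bchCXYZ",
    "orientation": "reverse",
    "n_members": 5
   },
   {
    "name": "bchO",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "ppsR",
    "orientation": "reverse",
    "n_members": 1
   },
   {
    "name": "aerR",
    "orientation": "forward",
    "n_members": 1
   },
   {
    "name": "bchID",
    "orientation": "forward",
    "n_members": 2
   }
  ]
 }
]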