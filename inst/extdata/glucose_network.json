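{
  "metabolites": [
    {
      "id": "glc",
      "name": "imported glucose",
      "role": "source"
    },
    {
      "id": "g6p",
      "name": "glucose-6-phosphate",
      "role": "internal"
    },
    {
      "id": "f6p",
      "name": "fructose-6-phosphate",
      "role": "internal"
    },
    {
      "id": "udpglcnac",
      "name": "UDP-GlcNAc",
      "role": "internal"
    },
    {
      "id": "g3p",
      "name": "glyceraldehyde-3-phosphate",
      "role": "internal"
    },
    {
      "id": "pg3",
      "name": "3-phosphoglycerate",
      "role": "internal"
    },
    {
      "id": "ser",
      "name": "serine",
      "role": "internal"
    },
    {
      "id": "cer",
      "name": "ceramide",
      "role": "internal"
    },
    {
      "id": "pyr",
      "name": "pyruvate",
      "role": "internal"
    },
    {
      "id": "accoa",
      "name": "acetyl-CoA",
      "role": "internal"
    },
    {
      "id": "cit",
      "name": "citrate",
      "role": "internal"
    }
  ],
  "reactions": [
    {
      "id": "r_glc_uptake",
      "stoichiometry": {
        "glc": -1,
        "g6p": 1
      },
      "ec": "2.7.1.1",
      "genes": ["SLC2A1", "SLC2A3", "SLC5A1", "SLC5A2", "SLC2A10", "HK1", "HK2"],
      "proton_coefficient": 1,
      "pathway": "internal"
    },
    {
      "id": "r_g6p_f6p",
      "stoichiometry": {
        "g6p": -1,
        "f6p": 1
      },
      "ec": "5.3.1.9",
      "genes": "GPI",
      "proton_coefficient": 0,
      "pathway": "internal"
    },
    {
      "id": "r_f6p_udpglcnac",
      "stoichiometry": {
        "f6p": -1,
        "udpglcnac": 1
      },
      "ec": "2.6.1.16",
      "genes": ["GFPT1", "GFPT2", "PGM3", "UAP1"],
      "proton_coefficient": 0,
      "pathway": "internal"
    },
    {
      "id": "r_f6p_g3p",
      "stoichiometry": {
        "f6p": -1,
        "g3p": 1
      },
      "ec": "2.7.1.11",
      "genes": ["PFKL", "PFKM", "ALDOA", "TPI1"],
      "proton_coefficient": 1,
      "pathway": "internal"
    },
    {
      "id": "r_g3p_pg3",
      "stoichiometry": {
        "g3p": -1,
        "pg3": 1
      },
      "ec": "1.2.1.12",
      "genes": ["GAPDH", "PGK1"],
      "proton_coefficient": 1,
      "pathway": "internal"
    },
    {
      "id": "r_pg3_ser",
      "stoichiometry": {
        "pg3": -1,
        "ser": 1
      },
      "ec": "1.1.1.95",
      "genes": ["PHGDH", "PSAT1", "PSPH"],
      "proton_coefficient": 0,
      "pathway": "internal"
    },
    {
      "id": "r_ser_cer",
      "stoichiometry": {
        "ser": -1,
        "cer": 1
      },
      "ec": "2.3.1.50",
      "genes": ["SPTLC1", "SPTLC2", "CERS2"],
      "proton_coefficient": 0,
      "pathway": "internal"
    },
    {
      "id": "r_pg3_pyr",
      "stoichiometry": {
        "pg3": -1,
        "pyr": 1
      },
      "ec": "2.7.1.40",
      "genes": ["PGAM1", "ENO1", "PKM"],
      "proton_coefficient": 1,
      "pathway": "internal"
    },
    {
      "id": "r_pyr_accoa",
      "stoichiometry": {
        "pyr": -1,
        "accoa": 1
      },
      "ec": "1.2.4.1",
      "genes": ["PDHA1", "PDHB", "DLAT"],
      "proton_coefficient": 0,
      "pathway": "internal"
    },
    {
      "id": "r_accoa_cit",
      "stoichiometry": {
        "accoa": -1,
        "cit": 1
      },
      "ec": "2.3.3.1",
      "genes": "CS",
      "proton_coefficient": 1,
      "pathway": "internal"
    },
    {
      "id": "r_sink_nucleotide_synthesis",
      "stoichiometry": {
        "g6p": -1
      },
      "ec": "1.1.1.49",
      "genes": ["G6PD", "PGD", "PRPS1", "PPAT"],
      "proton_coefficient": 8,
      "pathway": "nucleotide_synthesis"
    },
    {
      "id": "r_sink_glycosylation",
      "stoichiometry": {
        "udpglcnac": -1
      },
      "ec": "2.4.1.255",
      "genes": ["OGT", "MGAT1", "ALG1"],
      "proton_coefficient": 0,
      "pathway": "glycosylation"
    },
    {
      "id": "r_sink_sialic_acid",
      "stoichiometry": {
        "udpglcnac": -1
      },
      "ec": "2.5.1.56",
      "genes": ["GNE", "NANS", "CMAS", "ST3GAL1"],
      "proton_coefficient": 2,
      "pathway": "sialic_acid"
    },
    {
      "id": "r_sink_lipid_synthesis",
      "stoichiometry": {
        "g3p": -1
      },
      "ec": "2.3.1.15",
      "genes": ["GPAT3", "AGPAT2", "DGAT1", "FASN", "SCD"],
      "proton_coefficient": -1,
      "pathway": "lipid_synthesis"
    },
    {
      "id": "r_sink_serine_synthesis",
      "stoichiometry": {
        "ser": -1
      },
      "ec": "2.1.2.1",
      "genes": ["SHMT1", "SHMT2"],
      "proton_coefficient": 0,
      "pathway": "serine_synthesis"
    },
    {
      "id": "r_sink_ganglioside_synthesis",
      "stoichiometry": {
        "cer": -1
      },
      "ec": "2.4.1.80",
      "genes": ["UGCG", "B4GALT5", "ST3GAL5"],
      "proton_coefficient": 1,
      "pathway": "ganglioside_synthesis"
    },
    {
      "id": "r_sink_lactate",
      "stoichiometry": {
        "pyr": -1
      },
      "ec": "1.1.1.27",
      "genes": ["LDHA", "LDHB", "SLC16A1"],
      "proton_coefficient": 1,
      "pathway": "lactate"
    },
    {
      "id": "r_sink_tca_cycle",
      "stoichiometry": {
        "cit": -1
      },
      "ec": "4.2.1.3",
      "genes": ["ACO2", "IDH2"],
      "proton_coefficient": 1,
      "pathway": "tca_cycle"
    }
  ]
}
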