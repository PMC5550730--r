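{
  "_schema": {
    "Cm": "membrane capacitance, uF/cm^2",
    "channels": "per channel: g (max conductance, mS/cm^2), E (reversal, mV), M (activation exponent), N (inactivation exponent), gates (activation/inactivation gating modes)",
    "ahp": "calcium-dependent K current: g (mS/cm^2), k1 (half-activation Ca)",
    "ca": "intracellular calcium: eps (1/ms scaling), kca (removal rate)",
    "phi": "temperature-like factors on dynamic gate kinetics",
    "bias": "constant bias current, uA/cm^2, per condition",
    "_note": "Channel tables as printed for this model; gating kinetics functional forms adopted from the Rubin & Terman (2004) / So et al. (2012) model family."
  },
  "TH": {
    "Cm": 1.0,
    "channels": {
      "L": {
        "g": 0.05,
        "E": -70,
        "M": 0,
        "N": 0,
        "gates": "none"
      },
      "Na": {
        "g": 3,
        "E": 50,
        "M": 3,
        "N": 1,
        "gates": "m instantaneous, h dynamic"
      },
      "K": {
        "g": 5,
        "E": -75,
        "M": 4,
        "N": 0,
        "gates": "gate = 0.75*(1-h), slaved to Na inactivation"
      },
      "T": {
        "g": 5,
        "E": 0,
        "M": 2,
        "N": 1,
        "gates": "p instantaneous, r dynamic"
      }
    },
    "bias": {
      "healthy": 0,
      "pd": 0
    }
  },
  "STN": {
    "Cm": 1.0,
    "channels": {
      "L": {
        "g": 2.25,
        "E": -60,
        "M": 0,
        "N": 0,
        "gates": "none"
      },
      "Na": {
        "g": 37,
        "E": 55,
        "M": 3,
        "N": 1,
        "gates": "m instantaneous, h dynamic"
      },
      "K": {
        "g": 45,
        "E": -80,
        "M": 4,
        "N": 0,
        "gates": "n dynamic"
      },
      "Ca": {
        "g": 2,
        "E": 140,
        "M": 2,
        "N": 0,
        "gates": "s instantaneous"
      },
      "T": {
        "g": 0.5,
        "E": 140,
        "M": 3,
        "N": 2,
        "gates": "a instantaneous, b slaved to dynamic r",
        "_note": "reversal tied to the calcium reversal as in the source models; required for the rebound-burst mechanism"
      }
    },
    "ahp": {
      "g": 9,
      "k1": 15
    },
    "ca": {
      "eps": 3.75e-05,
      "kca": 22.5
    },
    "phi": {
      "h": 0.75,
      "n": 0.75,
      "r": 0.2
    },
    "bias": {
      "healthy": 29,
      "pd": 20
    }
  },
  "GPe": {
    "Cm": 1.0,
    "channels": {
      "L": {
        "g": 0.1,
        "E": -65,
        "M": 0,
        "N": 0,
        "gates": "none"
      },
      "Na": {
        "g": 120,
        "E": 55,
        "M": 3,
        "N": 1,
        "gates": "m instantaneous, h dynamic"
      },
      "K": {
        "g": 30,
        "E": -80,
        "M": 4,
        "N": 0,
        "gates": "n dynamic"
      },
      "Ca": {
        "g": 0.15,
        "E": 120,
        "M": 2,
        "N": 0,
        "gates": "s instantaneous"
      },
      "T": {
        "g": 0.5,
        "E": 120,
        "M": 3,
        "N": 1,
        "gates": "a instantaneous, r dynamic",
        "_note": "reversal tied to the calcium reversal as in the source models"
      }
    },
    "ahp": {
      "g": 30,
      "k1": 30
    },
    "ca": {
      "eps": 0.0001,
      "kca": 15
    },
    "phi": {
      "h": 0.05,
      "n": 0.05,
      "r": 1.0
    },
    "bias": {
      "healthy": 20,
      "pd": 8
    }
  },
  "GPi": {
    "Cm": 1.0,
    "channels": {
      "L": {
        "g": 0.1,
        "E": -65,
        "M": 0,
        "N": 0,
        "gates": "none"
      },
      "Na": {
        "g": 120,
        "E": 55,
        "M": 3,
        "N": 1,
        "gates": "m instantaneous, h dynamic"
      },
      "K": {
        "g": 30,
        "E": -80,
        "M": 4,
        "N": 0,
        "gates": "n dynamic"
      },
      "Ca": {
        "g": 0.15,
        "E": 120,
        "M": 2,
        "N": 0,
        "gates": "s instantaneous"
      },
      "T": {
        "g": 0.5,
        "E": 120,
        "M": 3,
        "N": 1,
        "gates": "a instantaneous, r dynamic",
        "_note": "reversal tied to the calcium reversal as in the source models"
      }
    },
    "ahp": {
      "g": 30,
      "k1": 30
    },
    "ca": {
      "eps": 0.0001,
      "kca": 15
    },
    "phi": {
      "h": 0.05,
      "n": 0.05,
      "r": 1.0
    },
    "bias": {
      "healthy": 22,
      "pd": 12
    }
  },
  "synapses": {
    "kinetics": {
      "excitatory": {
        "alpha": 5,
        "beta": 1
      },
      "inhibitory": {
        "alpha": 2,
        "beta": 0.08
      },
      "activation": "H(Vpre) = 1/(1 + exp(-(Vpre + 20)/2))"
    },
    "projections": [
      {
        "pre": "GPi",
        "post": "TH",
        "g": 0.17,
        "E": -85,
        "sign": "inhibitory",
        "fanin": 1
      },
      {
        "pre": "GPe",
        "post": "STN",
        "g": 0.5,
        "E": -85,
        "sign": "inhibitory",
        "fanin": 2
      },
      {
        "pre": "STN",
        "post": "GPe",
        "g": 0.15,
        "E": 0,
        "sign": "excitatory",
        "fanin": 2
      },
      {
        "pre": "GPe",
        "post": "GPe",
        "g": 0.5,
        "E": -85,
        "sign": "inhibitory",
        "fanin": 2
      },
      {
        "pre": "STN",
        "post": "GPi",
        "g": 0.15,
        "E": 0,
        "sign": "excitatory",
        "fanin": 2
      },
      {
        "pre": "GPe",
        "post": "GPi",
        "g": 0.5,
        "E": -85,
        "sign": "inhibitory",
        "fanin": 2
      }
    ],
    "gpe_term_sign": 1
  },
  "stimulation": {
    "dbs_coupling": 1.0,
    "_note": "dimensionless electrode-to-membrane coupling efficiency applied to nominal DBS amplitudes (uA) to obtain injected current density (uA/cm^2); 1.0 treats printed uA amplitudes as uA/cm^2 on the unit-area compartment. A reduced value (~0.081) reproduces the published delay-threshold anchor instead; see the methods vignette."
  }
}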