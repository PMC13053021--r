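{
  "wood": {
    "label": "wood",
    "modes": [
      {
        "amplitude": 1,
        "frequency": 185.7,
        "decay": 18.65
      },
      {
        "amplitude": 0.7047,
        "frequency": 261.6,
        "decay": 19.55
      },
      {
        "amplitude": 0.4966,
        "frequency": 370.4,
        "decay": 25.67
      },
      {
        "amplitude": 0.3499,
        "frequency": 517.6,
        "decay": 26.75
      },
      {
        "amplitude": 0.2466,
        "frequency": 713,
        "decay": 29.37
      },
      {
        "amplitude": 0.1738,
        "frequency": 1084.3,
        "decay": 34.72
      },
      {
        "amplitude": 0.1225,
        "frequency": 1433.1,
        "decay": 39.46
      },
      {
        "amplitude": 0.0863,
        "frequency": 2119.2,
        "decay": 40.74
      },
      {
        "amplitude": 0.0608,
        "frequency": 2920.9,
        "decay": 50.67
      },
      {
        "amplitude": 0.0429,
        "frequency": 4005.3,
        "decay": 57.82
      }
    ]
  },
  "glass": {
    "label": "glass",
    "modes": [
      {
        "amplitude": 1,
        "frequency": 532.4,
        "decay": 4.16
      },
      {
        "amplitude": 0.7788,
        "frequency": 735.5,
        "decay": 4.19
      },
      {
        "amplitude": 0.6065,
        "frequency": 1001.4,
        "decay": 5.13
      },
      {
        "amplitude": 0.4724,
        "frequency": 1325.6,
        "decay": 4.95
      },
      {
        "amplitude": 0.3679,
        "frequency": 1746.2,
        "decay": 5.79
      },
      {
        "amplitude": 0.2865,
        "frequency": 2537.7,
        "decay": 5.98
      },
      {
        "amplitude": 0.2231,
        "frequency": 3435.5,
        "decay": 6.37
      },
      {
        "amplitude": 0.1738,
        "frequency": 4405.9,
        "decay": 7.99
      },
      {
        "amplitude": 0.1353,
        "frequency": 6084.6,
        "decay": 8
      },
      {
        "amplitude": 0.1054,
        "frequency": 8011,
        "decay": 9.17
      }
    ]
  },
  "cardboard": {
    "label": "cardboard",
    "modes": [
      {
        "amplitude": 1,
        "frequency": 113,
        "decay": 44.14
      },
      {
        "amplitude": 0.6376,
        "frequency": 166.5,
        "decay": 50.8
      },
      {
        "amplitude": 0.4066,
        "frequency": 233.5,
        "decay": 59.5
      },
      {
        "amplitude": 0.2592,
        "frequency": 329.9,
        "decay": 64.27
      },
      {
        "amplitude": 0.1653,
        "frequency": 460.7,
        "decay": 72.3
      },
      {
        "amplitude": 0.1054,
        "frequency": 611.5,
        "decay": 73.85
      },
      {
        "amplitude": 0.0672,
        "frequency": 822.8,
        "decay": 73.49
      },
      {
        "amplitude": 0.0429,
        "frequency": 1136.7,
        "decay": 86.04
      },
      {
        "amplitude": 0.0273,
        "frequency": 1512.6,
        "decay": 105.45
      },
      {
        "amplitude": 0.0174,
        "frequency": 2075.9,
        "decay": 111.47
      }
    ]
  },
  "metal": {
    "label": "metal",
    "modes": [
      {
        "amplitude": 1,
        "frequency": 427.6,
        "decay": 2.09
      },
      {
        "amplitude": 0.8187,
        "frequency": 577.8,
        "decay": 1.97
      },
      {
        "amplitude": 0.6703,
        "frequency": 781.7,
        "decay": 2.63
      },
      {
        "amplitude": 0.5488,
        "frequency": 1109.3,
        "decay": 2.74
      },
      {
        "amplitude": 0.4493,
        "frequency": 1605.2,
        "decay": 2.61
      },
      {
        "amplitude": 0.3679,
        "frequency": 2131.5,
        "decay": 3.2
      },
      {
        "amplitude": 0.3012,
        "frequency": 3203.3,
        "decay": 3.37
      },
      {
        "amplitude": 0.2466,
        "frequency": 4599.3,
        "decay": 2.99
      },
      {
        "amplitude": 0.2019,
        "frequency": 6260.9,
        "decay": 3.94
      },
      {
        "amplitude": 0.1653,
        "frequency": 8689.4,
        "decay": 4.33
      }
    ]
  }
}
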