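{
  "comment": "Synthetic daily-living scenario: five taggable activities plus an untagged idle class (~45% of each day). Accelerations in g, durations in seconds, oscillation frequencies in Hz. The 'still' regime is shared by working, dinner and idle; the commuting class is fragmented (one regime per episode) and its 'walk' regime coincides with the exercise class's walking regime.",
  "sampling_rate": 20,
  "classes": [
    {
      "name": "working",
      "min_duration": 360,
      "max_duration": 720,
      "fragmented": false,
      "regimes": [
        {
          "name": "desk",
          "weight": 0.75,
          "mean": [
            0.05,
            -0.55,
            0.8
          ],
          "sd": [
            0.07,
            0.06,
            0.06
          ],
          "freq": 0,
          "amp": [
            0,
            0,
            0
          ],
          "bout_s": 12
        },
        {
          "name": "still",
          "weight": 0.25,
          "mean": [
            -0.1,
            -0.2,
            0.95
          ],
          "sd": [
            0.04,
            0.04,
            0.04
          ],
          "freq": 0,
          "amp": [
            0,
            0,
            0
          ],
          "bout_s": 6
        }
      ]
    },
    {
      "name": "dinner",
      "min_duration": 240,
      "max_duration": 420,
      "fragmented": false,
      "regimes": [
        {
          "name": "gesture",
          "weight": 0.8,
          "mean": [
            0.5,
            -0.25,
            0.6
          ],
          "sd": [
            0.16,
            0.14,
            0.13
          ],
          "freq": 0.8,
          "amp": [
            0.15,
            0.12,
            0.1
          ],
          "bout_s": 8
        },
        {
          "name": "still",
          "weight": 0.2,
          "mean": [
            -0.1,
            -0.2,
            0.95
          ],
          "sd": [
            0.04,
            0.04,
            0.04
          ],
          "freq": 0,
          "amp": [
            0,
            0,
            0
          ],
          "bout_s": 4
        }
      ]
    },
    {
      "name": "hygiene",
      "min_duration": 150,
      "max_duration": 240,
      "fragmented": false,
      "regimes": [
        {
          "name": "brush",
          "weight": 0.8,
          "mean": [
            0.45,
            0.25,
            0.55
          ],
          "sd": [
            0.3,
            0.3,
            0.25
          ],
          "freq": 3.0,
          "amp": [
            0.25,
            0.2,
            0.15
          ],
          "bout_s": 5
        },
        {
          "name": "still",
          "weight": 0.2,
          "mean": [
            -0.1,
            -0.2,
            0.95
          ],
          "sd": [
            0.04,
            0.04,
            0.04
          ],
          "freq": 0,
          "amp": [
            0,
            0,
            0
          ],
          "bout_s": 3
        }
      ]
    },
    {
      "name": "exercise",
      "min_duration": 300,
      "max_duration": 480,
      "fragmented": false,
      "regimes": [
        {
          "name": "walk",
          "weight": 0.55,
          "mean": [
            0.1,
            -0.3,
            0.9
          ],
          "sd": [
            0.28,
            0.3,
            0.26
          ],
          "freq": 1.8,
          "amp": [
            0.35,
            0.3,
            0.25
          ],
          "bout_s": 24
        },
        {
          "name": "run",
          "weight": 0.25,
          "mean": [
            0.15,
            -0.2,
            0.95
          ],
          "sd": [
            0.55,
            0.6,
            0.5
          ],
          "freq": 2.8,
          "amp": [
            0.6,
            0.55,
            0.5
          ],
          "bout_s": 12
        },
        {
          "name": "stretch",
          "weight": 0.05,
          "mean": [
            0.25,
            -0.1,
            0.85
          ],
          "sd": [
            0.1,
            0.1,
            0.1
          ],
          "freq": 0.3,
          "amp": [
            0.15,
            0.15,
            0.1
          ],
          "bout_s": 6
        },
        {
          "name": "pause",
          "weight": 0.15,
          "mean": [
            -0.1,
            -0.2,
            0.95
          ],
          "sd": [
            0.04,
            0.04,
            0.04
          ],
          "freq": 0,
          "amp": [
            0,
            0,
            0
          ],
          "bout_s": 8
        }
      ]
    },
    {
      "name": "commuting",
      "min_duration": 240,
      "max_duration": 400,
      "fragmented": true,
      "regimes": [
        {
          "name": "bus",
          "weight": 0.5,
          "mode": "bus",
          "mean": [
            -0.35,
            -0.75,
            0.5
          ],
          "sd": [
            0.09,
            0.09,
            0.09
          ],
          "freq": 3.5,
          "amp": [
            0.08,
            0.08,
            0.06
          ],
          "bout_s": 60
        },
        {
          "name": "walk",
          "weight": 0.375,
          "mode": "walk",
          "mean": [
            0.1,
            -0.3,
            0.9
          ],
          "sd": [
            0.28,
            0.3,
            0.26
          ],
          "freq": 1.8,
          "amp": [
            0.35,
            0.3,
            0.25
          ],
          "bout_s": 6
        },
        {
          "name": "pause",
          "weight": 0.125,
          "mode": "walk",
          "mean": [
            -0.1,
            -0.2,
            0.95
          ],
          "sd": [
            0.04,
            0.04,
            0.04
          ],
          "freq": 0,
          "amp": [
            0,
            0,
            0
          ],
          "bout_s": 2
        }
      ]
    },
    {
      "name": "idle",
      "min_duration": 150,
      "max_duration": 400,
      "fragmented": false,
      "regimes": [
        {
          "name": "still",
          "weight": 0.7,
          "mean": [
            -0.1,
            -0.2,
            0.95
          ],
          "sd": [
            0.04,
            0.04,
            0.04
          ],
          "freq": 0,
          "amp": [
            0,
            0,
            0
          ],
          "bout_s": 20
        },
        {
          "name": "fidget",
          "weight": 0.3,
          "mean": [
            -0.05,
            0.02,
            0.93
          ],
          "sd": [
            0.1,
            0.1,
            0.09
          ],
          "freq": 0,
          "amp": [
            0,
            0,
            0
          ],
          "bout_s": 6
        }
      ]
    }
  ]
}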