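{
  "years": [2002, 2003, 2004, 2005, 2006, 2007, 2008, 2009, 2010, 2011, 2012, 2013, 2014, 2015, 2016, 2017, 2018, 2019],
  "closure_year": 2010,
  "species": {
    "gull": {
      "baseline": 82,
      "slope_coupled": -0.4,
      "slope_buffered": 0,
      "resid_sd": 0.06,
      "buffer_extra_sd": 0.6,
      "buffered_before_closure": true,
      "n_clutches": 8,
      "eggs_per_clutch": 3,
      "clutch_sd": 1.5,
      "width_mean": 49,
      "width_sd": 1
    },
    "shearwater": {
      "baseline": 78,
      "slope_coupled": -0.4,
      "slope_buffered": 0,
      "resid_sd": 0.06,
      "buffer_extra_sd": 0,
      "buffered_before_closure": false,
      "n_clutches": 15,
      "eggs_per_clutch": 1,
      "clutch_sd": 1.5,
      "width_mean": 46.5,
      "width_sd": 1
    }
  },
  "env": {
    "mean": 0,
    "sd": 1,
    "ar": 0
  },
  "seed": 20260923
}
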