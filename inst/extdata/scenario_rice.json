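{
  "name": "rice",
  "version": 1,
  "comment": "Synthetic two-site flood-irrigated rice comparative trial. Cell means follow published posterior means of a comparable 25-genotype trial; every covariance component below is a package choice (no real variance inputs exist), set to give plot-level broad-sense heritability near 0.6 for both traits and a modest positive GY-FL genetic correlation (about 0.33).",
  "design": {
    "n_genotypes": 25,
    "environments": ["E1", "E2"],
    "blocks_per_environment": 3,
    "traits": ["GY", "FL"]
  },
  "beta": {
    "E1": { "GY": 4210.91, "FL": 99.40 },
    "E2": { "GY": 3901.56, "FL": 76.43 }
  },
  "genotype": { "sds": { "GY": 160.0, "FL": 2.5 }, "corr": 0.4 },
  "gxe":      { "sds": { "GY": 120.0, "FL": 1.8 }, "corr": 0.2 },
  "block":    { "sds": { "GY": 60.0,  "FL": 0.8 }, "corr": 0.0 },
  "residual": { "sds": { "GY": 150.0, "FL": 2.2 }, "corr": 0.1 }
}
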