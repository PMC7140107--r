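# Demo pipeline configuration: small synthetic genome, all five stages.
seed: 17
simulate:
  n_chrom: 2
  chrom_length: 3000000
  tracks:
    - name: LAD
      "n": 800  # quoted: bare n is YAML 1.1 shorthand for false
      length: 5000
      enrichment: 2.0
enrichment:
  n_permutations: 200
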