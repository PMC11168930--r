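# Demo synthetic chromosome: one qualifying palindrome, one satellite
# array large enough to become a SAT interval, and an ancestral gene.
# Run:  palindromekit synth --spec demo_spec.yaml --seed 1 --out-dir demo
chrom: chrDemo
length: 600000
features:
  - kind: palindrome
    start: 60000
    arm_len: 10000
    spacer_len: 5000
    divergence: 0.005
  - kind: satellite
    start: 200000
    unit_len: 171
    n_copies: 1600
  - kind: gene
    start: 550000
    length: 2000
    gene: GENE1
    class: ancestral
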