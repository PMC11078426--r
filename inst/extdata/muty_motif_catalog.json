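{
  "ref_id": "muty_ref_synthetic",
  "fasta": "muty_ref_synthetic.fasta",
  "split_before": 147,
  "comment": "Anchor coordinates follow Geobacillus-type MutY numbering; the backing sequence is a SYNTHETIC stand-in with anchor residues planted at these positions so the pipeline runs offline. Replace fasta/split_before/positions to use a real reference.",
  "anchors": [
    {
      "motif": "catalytic_glu",
      "positions": [43],
      "allowed": [["E"]],
      "role": "catalysis",
      "required": true
    },
    {
      "motif": "wedge_gln",
      "positions": [48],
      "allowed": [["Q"]],
      "role": "dna_binding",
      "required": true
    },
    {
      "motif": "wedge_tyr",
      "positions": [88],
      "allowed": [["Y"]],
      "role": "dna_binding",
      "required": true
    },
    {
      "motif": "ts_tyr",
      "positions": [126],
      "allowed": [["Y", "S", "T", "N"]],
      "role": "catalysis",
      "required": true
    },
    {
      "motif": "catalytic_asp",
      "positions": [144],
      "allowed": [["D", "E"]],
      "role": "catalysis",
      "required": true
    },
    {
      "motif": "small_linker",
      "positions": [145],
      "allowed": [["G", "A", "V", "T"]],
      "role": "catalysis",
      "required": true
    },
    {
      "motif": "catalytic_asn",
      "positions": [146],
      "allowed": [["N"]],
      "role": "catalysis",
      "required": true
    },
    {
      "motif": "iron_sulfur",
      "positions": [192, 199, 202, 208],
      "allowed": [["C"], ["C"], ["C"], ["C"]],
      "role": "cofactor",
      "required": true
    },
    {
      "motif": "l_xxx_p",
      "positions": [265, 269],
      "allowed": [["L", "M", "F"], ["P", "E"]],
      "role": "dna_binding",
      "required": true
    },
    {
      "motif": "og_recognition",
      "positions": [305, 306, 307, 308, 309],
      "allowed": [["H", "Q", "N", "R", "K"], ["*"], ["F"], ["S", "T"], ["H", "Q", "N", "R", "K"]],
      "role": "og_recognition",
      "required": true
    }
  ]
}
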