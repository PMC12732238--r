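{
  "format": "pepscreen-erap1-key/1",
  "authoritative": false,
  "note": "SYNTHETIC PLACEHOLDER key. The rsIDs and residue positions follow commonly cited ERAP1 coding variants, but the nucleotide alleles and the Hap1-Hap10 residue-state strings below are invented stand-ins so the calling machinery can be exercised offline. Replace this file with a transcription of the published haplotype definitions before interpreting real genotypes.",
  "snps": [
    {"rsid": "rs3734016",  "ref": "G", "alt": "A", "ref_residue": "E", "alt_residue": "K", "position": 56},
    {"rsid": "rs26653",    "ref": "C", "alt": "G", "ref_residue": "P", "alt_residue": "R", "position": 127},
    {"rsid": "rs26618",    "ref": "T", "alt": "C", "ref_residue": "I", "alt_residue": "M", "position": 276},
    {"rsid": "rs27895",    "ref": "G", "alt": "A", "ref_residue": "G", "alt_residue": "D", "position": 346},
    {"rsid": "rs2287987",  "ref": "A", "alt": "G", "ref_residue": "M", "alt_residue": "V", "position": 349},
    {"rsid": "rs30187",    "ref": "T", "alt": "C", "ref_residue": "K", "alt_residue": "R", "position": 528},
    {"rsid": "rs10050860", "ref": "C", "alt": "T", "ref_residue": "D", "alt_residue": "N", "position": 575},
    {"rsid": "rs17482078", "ref": "C", "alt": "T", "ref_residue": "R", "alt_residue": "Q", "position": 725},
    {"rsid": "rs27044",    "ref": "C", "alt": "G", "ref_residue": "Q", "alt_residue": "E", "position": 730}
  ],
  "haplotypes": {
    "Hap1":  "EPIGMKDRQ",
    "Hap2":  "ERIGMKDRE",
    "Hap3":  "ERIGMRDRE",
    "Hap4":  "KPIGMKDRQ",
    "Hap5":  "EPMGMKDRQ",
    "Hap6":  "ERIGVKNQE",
    "Hap7":  "EPIDMKDRQ",
    "Hap8":  "ERMGMRDRE",
    "Hap9":  "KPIGVKDRQ",
    "Hap10": "EPIGVRNQQ"
  }
}
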