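{
  "arriba": {
    "coordinate_convention": "1-based",
    "strip_leading_hash": true,
    "fields": {
      "gene5": {"column": "gene1"},
      "gene3": {"column": "gene2"},
      "chrom5": {"column": "breakpoint1", "sep": ":", "index": 1},
      "pos5": {"column": "breakpoint1", "sep": ":", "index": 2},
      "chrom3": {"column": "breakpoint2", "sep": ":", "index": 1},
      "pos3": {"column": "breakpoint2", "sep": ":", "index": 2},
      "strand5": {"column": "strand1(gene/fusion)", "sep": "/", "index": 2},
      "strand3": {"column": "strand2(gene/fusion)", "sep": "/", "index": 2},
      "split_reads": {"column": "split_reads"},
      "spanning_pairs": {"column": "discordant_mates"},
      "junction_seq": {"column": "fusion_transcript"},
      "frame": {"column": "reading_frame",
                "map": {"in-frame": "in-frame", "out-of-frame": "out-of-frame"}}
    }
  },
  "cicero": {
    "coordinate_convention": "1-based",
    "fields": {
      "gene5": {"column": "geneA"},
      "gene3": {"column": "geneB"},
      "chrom5": {"column": "chrA"},
      "pos5": {"column": "posA"},
      "chrom3": {"column": "chrB"},
      "pos3": {"column": "posB"},
      "strand5": {"column": "ortA"},
      "strand3": {"column": "ortB"},
      "reads": {"column": "readsA"},
      "junction_seq": {"column": "contig"}
    }
  },
  "fusionmap": {
    "coordinate_convention": "1-based",
    "fields": {
      "gene5": {"column": "KnownGene1"},
      "gene3": {"column": "KnownGene2"},
      "chrom5": {"column": "Chromosome1"},
      "pos5": {"column": "Position1"},
      "chrom3": {"column": "Chromosome2"},
      "pos3": {"column": "Position2"},
      "strand5": {"column": "Strand", "sep": "", "index": 1},
      "strand3": {"column": "Strand", "sep": "", "index": 2},
      "reads": {"column": "SeedCount"}
    }
  },
  "fusioncatcher": {
    "coordinate_convention": "1-based",
    "fields": {
      "gene5": {"column": "Gene_1_symbol(5end_fusion_partner)"},
      "gene3": {"column": "Gene_2_symbol(3end_fusion_partner)"},
      "chrom5": {"column": "Fusion_point_for_gene_1(5end_fusion_partner)", "sep": ":", "index": 1},
      "pos5": {"column": "Fusion_point_for_gene_1(5end_fusion_partner)", "sep": ":", "index": 2},
      "strand5": {"column": "Fusion_point_for_gene_1(5end_fusion_partner)", "sep": ":", "index": 3},
      "chrom3": {"column": "Fusion_point_for_gene_2(3end_fusion_partner)", "sep": ":", "index": 1},
      "pos3": {"column": "Fusion_point_for_gene_2(3end_fusion_partner)", "sep": ":", "index": 2},
      "strand3": {"column": "Fusion_point_for_gene_2(3end_fusion_partner)", "sep": ":", "index": 3},
      "split_reads": {"column": "Spanning_unique_reads"},
      "spanning_pairs": {"column": "Spanning_pairs"},
      "frame": {"column": "Predicted_effect",
                "map": {"in-frame": "in-frame", "out-of-frame": "out-of-frame"}}
    }
  },
  "jaffa": {
    "coordinate_convention": "1-based",
    "fields": {
      "gene5": {"column": "fusion genes", "sep": ":", "index": 1},
      "gene3": {"column": "fusion genes", "sep": ":", "index": 2},
      "chrom5": {"column": "chrom1"},
      "pos5": {"column": "base1"},
      "strand5": {"column": "strand1"},
      "chrom3": {"column": "chrom2"},
      "pos3": {"column": "base2"},
      "strand3": {"column": "strand2"},
      "split_reads": {"column": "spanning reads"},
      "spanning_pairs": {"column": "spanning pairs"},
      "frame": {"column": "inFrame",
                "map": {"TRUE": "in-frame", "FALSE": "out-of-frame"}}
    }
  },
  "mapsplice": {
    "coordinate_convention": "0-based",
    "fields": {
      "gene5": {"column": "annotated_gene_donor"},
      "gene3": {"column": "annotated_gene_acceptor"},
      "chrom5": {"column": "chrom", "sep": "~", "index": 1},
      "chrom3": {"column": "chrom", "sep": "~", "index": 2},
      "pos5": {"column": "doner_end"},
      "pos3": {"column": "acceptor_start"},
      "strand5": {"column": "strand", "sep": "", "index": 1},
      "strand3": {"column": "strand", "sep": "", "index": 2},
      "reads": {"column": "coverage"}
    }
  },
  "starfusion": {
    "coordinate_convention": "1-based",
    "strip_leading_hash": true,
    "fields": {
      "gene5": {"column": "FusionName", "sep": "--", "index": 1},
      "gene3": {"column": "FusionName", "sep": "--", "index": 2},
      "chrom5": {"column": "LeftBreakpoint", "sep": ":", "index": 1},
      "pos5": {"column": "LeftBreakpoint", "sep": ":", "index": 2},
      "strand5": {"column": "LeftBreakpoint", "sep": ":", "index": 3},
      "chrom3": {"column": "RightBreakpoint", "sep": ":", "index": 1},
      "pos3": {"column": "RightBreakpoint", "sep": ":", "index": 2},
      "strand3": {"column": "RightBreakpoint", "sep": ":", "index": 3},
      "split_reads": {"column": "JunctionReadCount"},
      "spanning_pairs": {"column": "SpanningFragCount"}
    }
  }
}
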