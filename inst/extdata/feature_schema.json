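{
  "snv": ["status_meta", "called_by_tracker", "called_by_caller_a", "called_by_caller_b", "depth", "alt_count", "vaf", "mean_mapq_alt", "mean_baseq_alt", "strand_bias_phred", "spans_indel", "mean_read_pos_fraction", "homopolymer_len", "in_str", "in_low_complexity", "gc_content_101bp", "maf_db1", "maf_db2", "maf_db3", "maf_db4", "max_germline_maf", "cosmic_match", "cosmic_freq", "is_transition", "consequence_class", "base_change_class"],
  "indel": ["status_meta", "called_by_tracker", "called_by_caller_a", "called_by_caller_b", "depth", "alt_count", "vaf", "mean_mapq_alt", "mean_baseq_alt", "strand_bias_phred", "spans_indel", "homopolymer_len", "in_str", "in_low_complexity", "gc_content_101bp", "maf_db1", "maf_db2", "maf_db3", "maf_db4", "max_germline_maf", "cosmic_match", "cosmic_freq", "consequence_class", "indel_length"],
  "classes": ["CHIP", "GERMLINE", "ARTIFACT"],
  "consequence_codes": {
    "noncoding": 0,
    "synonymous": 1,
    "missense": 2,
    "inframe_indel": 3,
    "stop_loss": 4,
    "start_loss": 5,
    "essential_splice": 6,
    "frameshift": 7,
    "nonsense": 8
  }
}
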