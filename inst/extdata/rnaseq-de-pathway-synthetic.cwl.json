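{
  "class": "Workflow",
  "cwlVersion": "v1.2",
  "id": "rnaseq_de_pathway_synthetic",
  "label": "RNA-seq differential expression and pathway analysis (synthetic stand-in)",
  "doc": "Synthetic four-step RNA-seq workflow emulating the structure of the deposited rnaseq-de-pathway workflow: raw FASTQ files through trimming/QC, alignment and quantification, differential expression, and pathway enrichment. Authored for offline testing; not the deposited document.",
  "inputs": [
    {"id": "fastq_files", "type": {"type": "array", "items": "File"}, "label": "raw FASTQ files"},
    {"id": "reference_index", "type": "File", "label": "aligner reference index"},
    {"id": "gene_annotation", "type": "File", "label": "gene annotation (GTF)"},
    {"id": "sample_metadata", "type": "File", "label": "sample sheet with conditions"},
    {"id": "contrast", "type": "string", "label": "DE contrast, e.g. failing-vs-control"}
  ],
  "outputs": [
    {"id": "qc_reports", "type": {"type": "array", "items": "File"}, "outputSource": "trim_and_qc/reports"},
    {"id": "gene_counts", "type": "File", "outputSource": "align_and_quantify/counts"},
    {"id": "de_results", "type": "File", "outputSource": "differential_expression/results"},
    {"id": "pathway_results", "type": "File", "outputSource": "pathway_enrichment/results"}
  ],
  "steps": [
    {
      "id": "trim_and_qc",
      "doc": "adapter/quality trimming and per-sample QC reports",
      "run": "tools/trim-and-qc.cwl",
      "in": [
        {"id": "reads", "source": "fastq_files"},
        {"id": "min_quality", "default": 20},
        {"id": "min_length", "default": 35}
      ],
      "out": ["trimmed_reads", "reports"]
    },
    {
      "id": "align_and_quantify",
      "doc": "splice-aware alignment and gene-level quantification",
      "run": "tools/align-quantify.cwl",
      "in": [
        {"id": "reads", "source": "trim_and_qc/trimmed_reads"},
        {"id": "index", "source": "reference_index"},
        {"id": "annotation", "source": "gene_annotation"},
        {"id": "threads", "default": 8}
      ],
      "out": ["alignments", "counts"]
    },
    {
      "id": "differential_expression",
      "doc": "negative-binomial differential expression between conditions",
      "run": "tools/deseq.cwl",
      "in": [
        {"id": "counts", "source": "align_and_quantify/counts"},
        {"id": "metadata", "source": "sample_metadata"},
        {"id": "contrast", "source": "contrast"},
        {"id": "alpha", "default": 0.05}
      ],
      "out": ["results"]
    },
    {
      "id": "pathway_enrichment",
      "doc": "pathway over-representation analysis of DE genes",
      "run": "tools/pathway-enrichment.cwl",
      "in": [
        {"id": "de_table", "source": "differential_expression/results"},
        {"id": "fdr_cutoff", "default": 0.1}
      ],
      "out": ["results"]
    }
  ]
}
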