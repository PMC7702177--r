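{
  "task_id": "task-1",
  "task_name": "rnaseq demo execution",
  "app_name": "rnaseq_de_pathway_synthetic",
  "app_revision": "3",
  "platform_name": "mock-platform",
  "project": "demo/rnaseq",
  "status": "completed",
  "start": "2020-02-01T09:00:00Z",
  "end": "2020-02-01T11:30:00Z",
  "inputs": [
    {"name": "fastq_files", "value": [
      {"class": "File", "path": "platform://files/sample1_R1.fastq.gz", "name": "sample1_R1.fastq.gz"},
      {"class": "File", "path": "platform://files/sample1_R2.fastq.gz", "name": "sample1_R2.fastq.gz"}
    ]},
    {"name": "reference_index", "value": {"class": "File", "path": "platform://files/grch38_index.tar", "name": "grch38_index.tar"}},
    {"name": "trim_and_qc/min_quality", "value": 20},
    {"name": "align_and_quantify/threads", "value": 8},
    {"name": "differential_expression/alpha", "value": 0.05}
  ],
  "outputs": [
    {"class": "File", "path": "platform://files/de_results.tsv", "name": "de_results.tsv"},
    {"class": "File", "path": "platform://files/pathway_results.tsv", "name": "pathway_results.tsv"}
  ]
}
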