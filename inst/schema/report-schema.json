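{
  "type": "object",
  "required": ["provenance", "stages", "summary"],
  "properties": {
    "provenance": {
      "type": "object",
      "required": ["package", "version", "seed", "config", "selection", "input"],
      "properties": {
        "package": {"type": "string"},
        "version": {"type": "string"},
        "seed": {"type": "integer"},
        "config": {
          "type": "object",
          "required": ["rmsd_cutoff_A", "n_pca_components", "stride"],
          "properties": {
            "rmsd_cutoff_A": {"type": "number"},
            "n_pca_components": {"type": "integer"},
            "stride": {"type": "integer"}
          }
        },
        "selection": {"type": "string"},
        "input": {
          "type": "object",
          "required": ["n_frames", "n_atoms", "coord_checksum"],
          "properties": {
            "n_frames": {"type": "integer"},
            "n_atoms": {"type": "integer"},
            "coord_checksum": {"type": "string"}
          }
        }
      }
    },
    "stages": {
      "type": "object",
      "required": ["rmsd_series", "rmsd_matrix", "clusters", "pca", "rmsf",
                   "tica", "gauges"],
      "properties": {
        "rmsd_series": {"type": "object", "required": ["completed"]},
        "rmsd_matrix": {"type": "object", "required": ["completed"]},
        "clusters": {"type": "object", "required": ["completed"]},
        "pca": {"type": "object", "required": ["completed"]},
        "rmsf": {"type": "object", "required": ["completed"]},
        "tica": {"type": "object", "required": ["completed"]},
        "gauges": {"type": "object", "required": ["completed"]}
      }
    },
    "summary": {
      "type": "object",
      "required": [],
      "properties": {
        "final_cluster_count": {"type": "integer"},
        "plateau_time_ns": {"type": "number"},
        "pca_explained_variance": {"type": "array"},
        "mean_rmsd_to_start_A": {"type": "number"}
      }
    }
  }
}
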