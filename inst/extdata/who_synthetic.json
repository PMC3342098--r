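{
  "algorithm_id": "who",
  "name": "WHO chronic-cough algorithm (synthetic reconstruction)",
  "entry": "entry",
  "nodes": [
    {
      "id": "entry",
      "kind": "clinical_state",
      "label": "HIV+ adult, cough > 3 weeks"
    },
    {
      "id": "smear",
      "kind": "other_action",
      "label": "Sputum smears x3 (serial)",
      "test": "sputum_smear3",
      "delay_days": 3
    },
    {
      "id": "d_smear",
      "kind": "decision",
      "label": "Smear positive?",
      "predicate": {
        "finding": "smear_result",
        "op": "equals",
        "value": ["positive"]
      }
    },
    {
      "id": "dx_tbsmear",
      "kind": "diagnostic_action",
      "label": "Treat smear-positive TB",
      "diagnosis": "tb_smear_pos"
    },
    {
      "id": "xray",
      "kind": "other_action",
      "label": "Chest X-ray",
      "test": "cxr",
      "delay_days": 1
    },
    {
      "id": "d_miliary",
      "kind": "decision",
      "label": "Miliary pattern?",
      "predicate": {
        "finding": "xray_pattern",
        "op": "equals",
        "value": ["miliary"]
      }
    },
    {
      "id": "dx_miliary",
      "kind": "diagnostic_action",
      "label": "Treat miliary TB",
      "diagnosis": "miliary_tb"
    },
    {
      "id": "d_effusion",
      "kind": "decision",
      "label": "Pleural effusion?",
      "predicate": {
        "finding": "xray_pattern",
        "op": "equals",
        "value": ["effusion"]
      }
    },
    {
      "id": "dx_pleural",
      "kind": "diagnostic_action",
      "label": "Tap and treat as pleural TB",
      "diagnosis": "pleural_tb"
    },
    {
      "id": "d_kaposi",
      "kind": "decision",
      "label": "Mucocutaneous Kaposi lesions?",
      "predicate": {
        "finding": "kaposi_lesions",
        "op": "present"
      }
    },
    {
      "id": "dx_kaposi",
      "kind": "diagnostic_action",
      "label": "Refer for Kaposi's sarcoma",
      "diagnosis": "kaposi"
    },
    {
      "id": "d_interstitial",
      "kind": "decision",
      "label": "Diffuse interstitial infiltrate?",
      "predicate": {
        "finding": "xray_pattern",
        "op": "equals",
        "value": ["interstitial"]
      }
    },
    {
      "id": "dx_pcp",
      "kind": "diagnostic_action",
      "label": "Treat pneumocystosis",
      "diagnosis": "pcp"
    },
    {
      "id": "d_lobar",
      "kind": "decision",
      "label": "Lobar consolidation?",
      "predicate": {
        "finding": "xray_pattern",
        "op": "equals",
        "value": ["consolidation_lobar"]
      }
    },
    {
      "id": "dx_lobar",
      "kind": "diagnostic_action",
      "label": "Treat lobar pneumonia",
      "diagnosis": "lobar_pneumonia"
    },
    {
      "id": "d_patchy",
      "kind": "decision",
      "label": "Patchy infiltrate?",
      "predicate": {
        "finding": "xray_pattern",
        "op": "equals",
        "value": ["consolidation_patchy"]
      }
    },
    {
      "id": "dx_atypical",
      "kind": "diagnostic_action",
      "label": "Treat atypical pneumonia",
      "diagnosis": "atypical_pneumonia"
    },
    {
      "id": "refer",
      "kind": "other_action",
      "label": "Refer to clinician judgement"
    }
  ],
  "edges": [
    {
      "from": "entry",
      "to": "smear",
      "branch": "next",
      "backward": false
    },
    {
      "from": "smear",
      "to": "d_smear",
      "branch": "next",
      "backward": false
    },
    {
      "from": "d_smear",
      "to": "dx_tbsmear",
      "branch": "yes",
      "backward": false
    },
    {
      "from": "d_smear",
      "to": "xray",
      "branch": "no",
      "backward": false
    },
    {
      "from": "xray",
      "to": "d_miliary",
      "branch": "next",
      "backward": false
    },
    {
      "from": "d_miliary",
      "to": "dx_miliary",
      "branch": "yes",
      "backward": false
    },
    {
      "from": "d_miliary",
      "to": "d_effusion",
      "branch": "no",
      "backward": false
    },
    {
      "from": "d_effusion",
      "to": "dx_pleural",
      "branch": "yes",
      "backward": false
    },
    {
      "from": "d_effusion",
      "to": "d_kaposi",
      "branch": "no",
      "backward": false
    },
    {
      "from": "d_kaposi",
      "to": "dx_kaposi",
      "branch": "yes",
      "backward": false
    },
    {
      "from": "d_kaposi",
      "to": "d_interstitial",
      "branch": "no",
      "backward": false
    },
    {
      "from": "d_interstitial",
      "to": "dx_pcp",
      "branch": "yes",
      "backward": false
    },
    {
      "from": "d_interstitial",
      "to": "d_lobar",
      "branch": "no",
      "backward": false
    },
    {
      "from": "d_lobar",
      "to": "dx_lobar",
      "branch": "yes",
      "backward": false
    },
    {
      "from": "d_lobar",
      "to": "d_patchy",
      "branch": "no",
      "backward": false
    },
    {
      "from": "d_patchy",
      "to": "dx_atypical",
      "branch": "yes",
      "backward": false
    },
    {
      "from": "d_patchy",
      "to": "refer",
      "branch": "no",
      "backward": false
    }
  ]
}
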