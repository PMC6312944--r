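{
  "wards": [
    {
      "id": "ed",
      "name": "Emergency Department",
      "capacity": 20,
      "resources": 50,
      "los_lambda": 2,
      "need_lambda": 2,
      "queue_policy": "chronological",
      "resource_policy": "even",
      "allow_overflow": false,
      "is_entry": true
    },
    {
      "id": "acute_assessment",
      "name": "Acute Assessment Unit",
      "capacity": 60,
      "resources": 30,
      "los_lambda": 24,
      "need_lambda": 24,
      "queue_policy": "chronological",
      "resource_policy": "even",
      "allow_overflow": false,
      "is_entry": false
    },
    {
      "id": "surgery",
      "name": "Surgery",
      "capacity": 40,
      "resources": 20,
      "los_lambda": 48,
      "need_lambda": 48,
      "queue_policy": "chronological",
      "resource_policy": "even",
      "allow_overflow": true,
      "is_entry": false
    },
    {
      "id": "cardiology",
      "name": "Cardiology",
      "capacity": 25,
      "resources": 15,
      "los_lambda": 48,
      "need_lambda": 48,
      "queue_policy": "chronological",
      "resource_policy": "even",
      "allow_overflow": false,
      "is_entry": false
    },
    {
      "id": "orthopaedics",
      "name": "Orthopaedics",
      "capacity": 25,
      "resources": 15,
      "los_lambda": 72,
      "need_lambda": 72,
      "queue_policy": "chronological",
      "resource_policy": "even",
      "allow_overflow": true,
      "is_entry": false
    },
    {
      "id": "general_medicine",
      "name": "General Medicine",
      "capacity": 30,
      "resources": 20,
      "los_lambda": 48,
      "need_lambda": 48,
      "queue_policy": "chronological",
      "resource_policy": "even",
      "allow_overflow": false,
      "is_entry": false
    },
    {
      "id": "geriatrics",
      "name": "Geriatrics",
      "capacity": 15,
      "resources": 18,
      "los_lambda": 96,
      "need_lambda": 96,
      "queue_policy": "chronological",
      "resource_policy": "even",
      "allow_overflow": false,
      "is_entry": false
    },
    {
      "id": "paediatrics",
      "name": "Paediatrics",
      "capacity": 5,
      "resources": 6,
      "los_lambda": 24,
      "need_lambda": 24,
      "queue_policy": "chronological",
      "resource_policy": "even",
      "allow_overflow": false,
      "is_entry": false
    }
  ],
  "graph": {
    "ed": {
      "acute_assessment": 0.35,
      "surgery": 0.07,
      "cardiology": 0.05,
      "orthopaedics": 0.05,
      "general_medicine": 0.08,
      "geriatrics": 0.03,
      "paediatrics": 0.04,
      "DISCHARGE": 0.33
    },
    "acute_assessment": {
      "general_medicine": 0.12,
      "surgery": 0.05,
      "cardiology": 0.05,
      "geriatrics": 0.05,
      "orthopaedics": 0.03,
      "DISCHARGE": 0.7
    },
    "surgery": {
      "orthopaedics": 0.05,
      "general_medicine": 0.1,
      "DISCHARGE": 0.85
    },
    "cardiology": {
      "general_medicine": 0.1,
      "DISCHARGE": 0.9
    },
    "orthopaedics": {
      "general_medicine": 0.08,
      "DISCHARGE": 0.92
    },
    "general_medicine": {
      "geriatrics": 0.12,
      "DISCHARGE": 0.88
    },
    "geriatrics": {
      "DISCHARGE": 1
    },
    "paediatrics": {
      "DISCHARGE": 1
    }
  },
  "settings": {
    "max_steps": 720,
    "arrivals_min": 0,
    "arrivals_max": 4,
    "waiting_time_target": 4,
    "seed": 42,
    "resource_unit_cost": 1,
    "bed_unit_cost": 2,
    "max_pathway_length": 20
  }
}
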