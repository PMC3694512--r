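{
  "id": "ehrest-TEMPLATE.encounter_bp.v1",
  "kind": "template",
  "root": {
    "name": "composition",
    "node_id": "openEHR-EHR-COMPOSITION.encounter.v1"
  },
  "nodes": [
    {
      "path": "/context",
      "min": 1,
      "max": 1
    },
    {
      "path": "/context/start_time",
      "min": 1,
      "max": 1,
      "value_kind": "timestamp"
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]",
      "min": 1,
      "max": 1
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]",
      "min": 1,
      "max": 4
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data[at0001]",
      "min": 1,
      "max": 1
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data[at0001]/events[at0006]",
      "min": 1,
      "max": 1
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data[at0001]/events[at0006]/time",
      "min": 1,
      "max": 1,
      "value_kind": "timestamp"
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data[at0001]/events[at0006]/data[at0003]",
      "min": 1,
      "max": 1
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data[at0001]/events[at0006]/data[at0003]/items[at0004]",
      "min": 1,
      "max": 1
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data[at0001]/events[at0006]/data[at0003]/items[at0004]/value",
      "min": 1,
      "max": 1,
      "value_kind": "quantity",
      "range": {
        "lower": 40,
        "upper": 280
      },
      "units": "mm[Hg]"
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data[at0001]/events[at0006]/data[at0003]/items[at0005]",
      "min": 1,
      "max": 1
    },
    {
      "path": "/content[openEHR-EHR-SECTION.vital_signs.v1]/items[openEHR-EHR-OBSERVATION.blood_pressure.v1]/data[at0001]/events[at0006]/data[at0003]/items[at0005]/value",
      "min": 1,
      "max": 1,
      "value_kind": "quantity",
      "range": {
        "lower": 20,
        "upper": 200
      },
      "units": "mm[Hg]"
    }
  ],
  "bases": [
    "openEHR-EHR-COMPOSITION.encounter.v1"
  ]
}
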