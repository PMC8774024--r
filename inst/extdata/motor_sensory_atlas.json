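{
  "name": "motor_sensory_28",
  "comment": "Synthetic stand-in parcellation of the motor-sensory network: 28 bilateral Brainnetome-style subregions of the precentral gyrus, paracentral lobule, postcentral gyrus and superior frontal gyrus. The exact 28-subregion membership used in the source study is not public; this fixture guarantees the ten subregion labels reported in its nodal tables.",
  "nodes": [
    {"id": "A4hf_L",      "hemisphere": "L", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A4hf_R",      "hemisphere": "R", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A4ul_L",      "hemisphere": "L", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A4ul_R",      "hemisphere": "R", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A4t_L",       "hemisphere": "L", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A4t_R",       "hemisphere": "R", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A4tl_L",      "hemisphere": "L", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A4tl_R",      "hemisphere": "R", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A6cdl_L",     "hemisphere": "L", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A6cdl_R",     "hemisphere": "R", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A6cvl_L",     "hemisphere": "L", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A6cvl_R",     "hemisphere": "R", "gyrus": "precentral gyrus",      "excluded": false},
    {"id": "A4ll_L",      "hemisphere": "L", "gyrus": "paracentral lobule",    "excluded": false},
    {"id": "A4ll_R",      "hemisphere": "R", "gyrus": "paracentral lobule",    "excluded": false},
    {"id": "A123ll_L",    "hemisphere": "L", "gyrus": "paracentral lobule",    "excluded": false},
    {"id": "A123ll_R",    "hemisphere": "R", "gyrus": "paracentral lobule",    "excluded": false},
    {"id": "A123ulhf_L",  "hemisphere": "L", "gyrus": "postcentral gyrus",     "excluded": false},
    {"id": "A123ulhf_R",  "hemisphere": "R", "gyrus": "postcentral gyrus",     "excluded": false},
    {"id": "A123tonIa_L", "hemisphere": "L", "gyrus": "postcentral gyrus",     "excluded": false},
    {"id": "A123tonIa_R", "hemisphere": "R", "gyrus": "postcentral gyrus",     "excluded": false},
    {"id": "A2_L",        "hemisphere": "L", "gyrus": "postcentral gyrus",     "excluded": false},
    {"id": "A2_R",        "hemisphere": "R", "gyrus": "postcentral gyrus",     "excluded": false},
    {"id": "A123tru_L",   "hemisphere": "L", "gyrus": "postcentral gyrus",     "excluded": false},
    {"id": "A123tru_R",   "hemisphere": "R", "gyrus": "postcentral gyrus",     "excluded": false},
    {"id": "A6m_L",       "hemisphere": "L", "gyrus": "superior frontal gyrus","excluded": false},
    {"id": "A6m_R",       "hemisphere": "R", "gyrus": "superior frontal gyrus","excluded": false},
    {"id": "A6dl_L",      "hemisphere": "L", "gyrus": "superior frontal gyrus","excluded": false},
    {"id": "A6dl_R",      "hemisphere": "R", "gyrus": "superior frontal gyrus","excluded": false}
  ],
  "default_exclusion": ["A6cdl_L", "A6cvl_L", "A6dl_L", "A4tl_L", "A123tonIa_L", "A2_L"]
}
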