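{
  "tests": {
    "ptosis": {
      "explanation": ["look up", "look up at the ceiling", "keep looking up",
                      "up at the ceiling", "look at the ceiling",
                      "eyes up", "gaze up"],
      "validation": ["keep holding", "hold it there", "keep your head still"]
    },
    "diplopia_right": {
      "explanation": ["look to the right", "look right", "look to your right",
                      "eyes to the right", "gaze to the right"],
      "validation": ["keep looking right", "hold your gaze"]
    },
    "diplopia_left": {
      "explanation": ["look to the left", "look left", "look to your left",
                      "eyes to the left", "gaze to the left"],
      "validation": ["keep looking left", "hold your gaze"]
    },
    "cheek_puff": {
      "explanation": ["puff your cheeks", "cheek puff", "puff out your cheeks",
                      "fill your cheeks with air", "puff up your cheeks"],
      "validation": ["hold the air", "keep them puffed"]
    },
    "tongue_to_cheek": {
      "explanation": ["tongue to cheek", "push your tongue into your cheek",
                      "tongue into your cheek", "tongue against your cheek",
                      "press your tongue"],
      "validation": ["push hard", "other side"]
    },
    "count_to_50": {
      "explanation": ["count to fifty", "count from one to fifty",
                      "count out loud to fifty", "count up to fifty",
                      "start counting to fifty"],
      "validation": ["keep counting", "normal pace"]
    },
    "arm_extension": {
      "explanation": ["extend your arms", "arms straight out",
                      "hold your arms out", "raise your arms",
                      "arms out to the side"],
      "validation": ["keep them up", "hold them there"]
    },
    "single_breath_count": {
      "explanation": ["single breath", "one breath", "deep breath",
                      "count on one breath", "as long as you can on one breath"],
      "validation": ["take a deep breath", "keep going"]
    },
    "sit_to_stand": {
      "explanation": ["arms crossed", "cross your arms",
                      "from the chair", "chair exercise",
                      "without using your hands"],
      "validation": ["stand up", "sit down", "stand back up", "sit back down"]
    },
    "adl": {"explanation": [], "validation": []}
  },
  "adl_questions": {
    "q1": ["slurred", "nasal", "speech"],
    "q2": ["fatigue", "jaw", "chewing"],
    "q3": ["choking", "swallowing"],
    "q4": ["shortness", "breath"],
    "q5": ["brushing", "teeth"],
    "q6": ["trouble", "chair", "toilet"],
    "q7": ["double", "vision"],
    "q8": ["drooping", "droopy", "eyelids"]
  }
}
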