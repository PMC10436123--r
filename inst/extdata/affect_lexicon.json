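{
  "__comment": "Small open affect lexicon, version 1. Lowercase literals or stems with a trailing '*' (prefix match). anxiety/anger/sadness are subcategories of negative affect; negative_other holds general negative words outside those subcategories.",
  "positive": ["happy", "happi*", "glad", "good", "great", "fun", "love*",
               "nice", "hope*", "joy*", "laugh*", "smil*", "enjoy*",
               "excit*", "wonderful", "awesome", "relax*", "cheer*",
               "delight*", "grateful", "proud", "sweet", "beautiful",
               "friend*", "comfort*", "pleas*", "amaz*", "fantastic"],
  "anxiety": ["worried", "worr*", "anxious*", "anxiet*", "nervous*",
              "afraid", "fear*", "scare*", "stress*", "tense", "panic*",
              "dread*", "uneasy", "overwhelm*", "restless", "frantic"],
  "anger": ["annoyed", "annoy*", "angry", "anger*", "mad", "madd*", "hate*",
            "furious", "rage*", "irritat*", "frustrat*", "outrag*",
            "resent*", "hostile", "bitter", "fuming"],
  "sadness": ["crying", "cry", "cried", "cries", "sad", "sadly", "sadness",
              "miserable", "grief*", "griev*", "lonely", "lonel*",
              "depress*", "gloomy", "tear*", "hopeless", "heartbroken",
              "mourn*", "sorrow*", "down", "blue"],
  "negative_other": ["hurt*", "ugly", "bad", "awful", "terrible", "nasty",
                     "wrong", "horrible", "gross", "disgust*", "fail*",
                     "problem*", "trouble*", "worthless", "stupid"]
}
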