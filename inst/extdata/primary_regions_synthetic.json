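{
  "primary": {
    "1": "CB",
    "2": "TH",
    "3": "MB",
    "4": "HB",
    "5": "Isocortex",
    "6": "HY",
    "7": "OLF",
    "8": "CTXsp",
    "9": "STR",
    "10": "PAL",
    "11": "HPF"
  },
  "map": {
    "1": 1,
    "2": 1,
    "3": 1,
    "4": 1,
    "5": 2,
    "6": 2,
    "7": 2,
    "8": 2,
    "9": 2,
    "10": 2,
    "11": 2,
    "12": 2,
    "13": 2,
    "14": 2,
    "15": 2,
    "16": 2,
    "17": 3,
    "18": 3,
    "19": 3,
    "20": 3,
    "21": 3,
    "22": 3,
    "23": 3,
    "24": 3,
    "25": 3,
    "26": 3,
    "27": 4,
    "28": 4,
    "29": 4,
    "30": 4,
    "31": 4,
    "32": 4,
    "33": 4,
    "34": 4,
    "35": 5,
    "36": 5,
    "37": 5,
    "38": 5,
    "39": 5,
    "40": 5,
    "41": 5,
    "42": 5,
    "43": 5,
    "44": 5,
    "45": 5,
    "46": 5,
    "47": 5,
    "48": 5,
    "49": 5,
    "50": 5,
    "51": 5,
    "52": 5,
    "53": 5,
    "54": 5,
    "55": 5,
    "56": 5,
    "57": 5,
    "58": 5,
    "59": 5,
    "60": 5,
    "61": 5,
    "62": 5,
    "63": 5,
    "64": 5,
    "65": 6,
    "66": 6,
    "67": 6,
    "68": 6,
    "69": 6,
    "70": 6,
    "71": 6,
    "72": 6,
    "73": 6,
    "74": 6,
    "75": 7,
    "76": 7,
    "77": 7,
    "78": 7,
    "79": 7,
    "80": 7,
    "81": 7,
    "82": 7,
    "83": 7,
    "84": 7,
    "85": 8,
    "86": 8,
    "87": 8,
    "88": 8,
    "89": 8,
    "90": 8,
    "91": 9,
    "92": 9,
    "93": 9,
    "94": 9,
    "95": 9,
    "96": 9,
    "97": 9,
    "98": 9,
    "99": 10,
    "100": 10,
    "101": 10,
    "102": 10,
    "103": 10,
    "104": 10,
    "105": 11,
    "106": 11,
    "107": 11,
    "108": 11,
    "109": 11,
    "110": 11,
    "111": 11,
    "112": 11,
    "113": 11,
    "114": 11,
    "115": 11,
    "116": 11,
    "117": 11,
    "118": 11
  }
}
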