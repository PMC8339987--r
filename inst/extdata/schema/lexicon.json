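{
  "Mass": ["肿块", "结节", "肿物", "占位", "团块影", "软组织肿块", "结节影", "肿块影"],
  "MassSmall": ["小结节", "结节", "小结节影", "微小结节", "结节灶"],
  "LymphNode": ["肿大淋巴结", "淋巴结肿大", "多发肿大淋巴结", "淋巴结增大", "多个肿大淋巴结"],
  "Negation": ["未见", "无", "未见明显", "未见确切", "不伴"],
  "Density": ["磨玻璃密度", "软组织密度", "混杂密度", "低密度", "实性密度", "磨玻璃样密度", "高密度"],
  "Enhancement": ["强化明显", "明显强化", "轻度强化", "中度强化", "不均匀强化", "环形强化", "均匀强化", "无明显强化"],
  "Shape": ["边缘见毛刺", "分叶状", "边界不清", "边缘光滑", "形态不规则", "边缘毛糙", "浅分叶", "边界清楚", "类圆形", "边缘见短毛刺"],
  "Bronchus": ["支气管狭窄", "支气管截断", "累及叶支气管", "支气管壁增厚", "支气管受压变窄", "叶支气管闭塞"],
  "PleuraInvasion": ["胸膜凹陷", "邻近胸膜牵拉", "累及胸膜", "胸膜增厚粘连", "侵犯胸膜", "胸膜牵拉凹陷"],
  "PleuraNodule": ["胸膜多发结节", "胸膜结节", "胸膜多发结节样增厚"],
  "Vessel": ["包绕左肺动脉", "侵犯肺动脉", "包绕降主动脉", "累及上腔静脉", "大血管受侵", "包绕右肺动脉干"],
  "VertebralBody": ["椎体骨质破坏", "邻近椎体受侵", "椎体见骨质破坏", "胸椎椎体破坏"],
  "Effusion": ["积液", "胸腔积液", "心包积液", "少量积液", "少量胸腔积液", "中量胸腔积液"],
  "PAOP": ["阻塞性肺不张", "肺组织不张", "阻塞性肺炎", "肺不张", "阻塞性炎症"],
  "Side": ["左", "右"],
  "Lobe": ["上叶", "中叶", "下叶"],
  "Segment": ["尖段", "后段", "前段", "基底段", "背段", "外侧段", "内侧段", "舌段"],
  "Verb": ["见", "可见", "另见", "显示"],
  "AboutMarker": ["约", "大小约", "大小为", "范围约"],
  "CleanLocation": ["余肺", "双肺余", "余肺内", "双肺其余肺野"],
  "CleanTail": ["异常阴影", "异常征象", "异常灶"],
  "Distractor": [
    "请结合临床随诊复查",
    "建议定期复查",
    "增强扫描呈上述表现",
    "双侧胸廓对称",
    "气管居中",
    "心脏形态大小在正常范围",
    "膈面光整",
    "对比剂注入顺利",
    "检查过程顺利",
    "图像质量满意"
  ]
}
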