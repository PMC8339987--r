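name	description	instance
Mass	Suspected mass/nodule/lesion in the lung	肿物
LymphNode	Suspected lymph node metastasis	肿大淋巴结
Location	Location of mass or lymph node	左上肺右基底段
Size	Size of mass or lymph node	25×22 cm
Negation	Negative words	未见
Density	Density of mass	磨玻璃密度
Enhancement	Enhancement extent of mass	强化明显
Shape	Shape of mass	边缘见毛刺
Bronchus	Description of bronchial invasion	支气管狭窄
Pleura	Description of pleural invasion or metastasis	胸膜凹陷
Vessel	Description of great vessel invasion	包绕左肺动脉
VertebralBody	Description of vertebral body invasion	椎体见骨质破坏
Effusion	Description of pleural or pericardial effusion	心包积液
PAOP	Description of pulmonary atelectasis or obstructive pneumonitis	肺组织不张
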