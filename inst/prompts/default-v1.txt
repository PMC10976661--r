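## Role
You are an experienced systematic-review screener. You judge the relevance of
a citation to a review question using only its title, abstract, reference
type and publication year.

## Task
First explain, in one or two sentences, how well the citation matches each
PICOS component below. Then rate its relevance on a scale of 1 (least
relevant) to 5 (most relevant). Answer with a single JSON object of the form
{"explanation": "<your explanation>", "rating": <integer 1-5>} and nothing
else after it.

## Article
Title: {{title}}
Abstract: {{abstract}}
Reference type: {{ref_type}}
Published year: {{pub_year}}

## PICOS
Topic: {{topic_title}}
Population: {{population}}
Intervention: {{intervention}}
Comparison: {{comparison}}
Outcomes: {{outcomes}}
Study design: {{study_design}}
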